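#' Run the full trait-space pipeline
#'
#' Composes the whole analysis in one reproducible call: standardize a
#' fuzzy-coded trait table group-wise to \[0,1\], fit the incomplete-data
#' centred PCA, select axes by the broken-stick rule, screen trait-axis
#' correlations, compute whole-assemblage and per-group convex-hull volumes,
#' run the three occupancy null models, and test taxonomic constraint with
#' PERMANOVA and PERMDISP. All numeric outputs are written as TSV files with
#' a JSON sidecar recording the configuration and seed, so identical
#' config + seed reproduces every file byte for byte.
#'
#' @param table a [fuzzy_trait_table()]; if `NULL`, a synthetic table is
#'   generated from `config` (with missingness injected at its configured
#'   rate).
#' @param config a [synthetic_config()] used when `table` is `NULL`.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param n_axes_hull number of leading axes spanning the geometric trait
#'   space (hull volumes and null models). Default 4, the number of
#'   interpretable axes in this kind of analysis; hull cost grows steeply
#'   with dimension, so raising this far beyond 5-6 is rarely practical.
#' @param n_axes_tests axis policy for the permutation tests:
#'   `"broken_stick"` uses the broken-stick-retained axes (at least 2), or
#'   give a fixed integer count.
#' @param standardization passed to [standardize_by_group()].
#' @param fraction centroid-trimming fraction for the null models.
#' @param null_models which of `"uniform"`, `"normal"`, `"permutation"` to
#'   run.
#' @param n_reps null-model replicates.
#' @param n_perms PERMANOVA/PERMDISP permutations.
#' @param seed master seed; per-stage seeds are derived from it, so adding a
#'   stage never changes another stage's randomness.
#' @return A list of class `traitspace_run` with elements `table`,
#'   `standardized`, `model` (the [ipca()] fit), `correlations`,
#'   `axis_summary`, `volumes` (untrimmed) and `volumes_trimmed`,
#'   `null_models` (one [null_model_test()] result per model),
#'   `relatedness` (the [run_relatedness_suite()] report), `n_axes_hull`,
#'   `n_axes_tests`, `out_dir`.
#' @export
run_pipeline <- function(table = NULL, config = synthetic_config(),
                         out_dir = NULL, n_axes_hull = 4L,
                         n_axes_tests = "broken_stick",
                         standardization = "max_code", fraction = 0.95,
                         null_models = c("uniform", "normal", "permutation"),
                         n_reps = 999L, seed = 1L, n_perms = 999L) {
  if (n_reps < 1) stop("'n_reps' must be at least 1")
  if (n_perms < 1) stop("'n_perms' must be at least 1")
  null_models <- match.arg(null_models, several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, ...) {
    message(sprintf("[%s] %s (%.1fs elapsed)", "traitspacer",
                    sprintf(name, ...), proc.time()[["elapsed"]] - t0))
  }
  if (is.null(table)) {
    config$seed <- substream_seed(seed, "synthetic")
    table <- simulate_fuzzy_table(config, missing = config$missing_rate > 0)
    stage("simulated %d taxa x %d traits", nrow(table$matrix), ncol(table$matrix))
  }
  std <- standardize_by_group(table, standardization)
  model <- ipca(std)
  stage("fitted incomplete PCA: %d broken-stick-significant axes", model$retained)
  k_hull <- min(as.integer(n_axes_hull), model$n_positive)
  k_tests <- if (identical(n_axes_tests, "broken_stick")) max(model$retained, 2L)
             else as.integer(n_axes_tests)
  k_tests <- min(k_tests, model$n_positive)
  if (k_hull < 2 || k_tests < 2) stop("need at least 2 axes")
  hull_scores <- model$scores[, seq_len(k_hull), drop = FALSE]
  test_scores <- model$scores[, seq_len(k_tests), drop = FALSE]
  corr <- trait_axis_correlations(std, model, n_axes = k_tests)
  axis_sum <- group_axis_summary(hull_scores, table$taxa$group,
                                 n_axes = min(4L, k_hull))
  vols <- group_volumes(hull_scores, table$taxa$group, trim = FALSE)
  vols_trim <- group_volumes(hull_scores, table$taxa$group, trim = TRUE,
                             fraction = fraction)
  stage("hull volumes on %d axes: whole assemblage %.3f (trimmed %.3f)", k_hull,
        vols$whole_volume, vols_trim$whole_volume)
  nulls <- lapply(null_models, function(m)
    null_model_test(hull_scores, m, n_reps = n_reps, fraction = fraction,
                    seed = substream_seed(seed, paste0("null_", m))))
  names(nulls) <- null_models
  for (m in null_models)
    stage("null model %s: occupancy %.2f%%, P = %.4g", m,
          nulls[[m]]$occupancy_percent, nulls[[m]]$p_value)
  grp_full <- if ("group_full" %in% names(table$taxa)) table$taxa$group_full
              else table$taxa$group
  related <- run_relatedness_suite(test_scores, table$taxa$group, grp_full,
                                   n_perms = n_perms,
                                   seed = substream_seed(seed, "relatedness"))
  stage("relatedness suite done")
  run <- structure(list(table = table, standardized = std, model = model,
                        correlations = corr, axis_summary = axis_sum,
                        volumes = vols, volumes_trimmed = vols_trim,
                        null_models = nulls, relatedness = related,
                        n_axes_hull = k_hull, n_axes_tests = k_tests,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "traitspace_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = run$seed, n_axes_hull = run$n_axes_hull,
               n_axes_tests = run$n_axes_tests,
               n_taxa = run$model$n_taxa, n_traits = run$model$n_variables,
               standardization = run$standardized$standardization)
  p <- function(f) file.path(out_dir, f)
  k <- max(run$n_axes_hull, run$n_axes_tests)
  scores <- as.data.frame(run$model$scores[, seq_len(k), drop = FALSE])
  write_tsv_with_meta(cbind(run$table$taxa, scores), p("scores.tsv"), meta)
  write_tsv_with_meta(
    data.frame(trait = rownames(run$model$loadings),
               run$model$loadings[, seq_len(k), drop = FALSE]),
    p("loadings.tsv"))
  write_tsv_with_meta(
    data.frame(axis = seq_along(run$model$eigenvalues),
               eigenvalue = run$model$eigenvalues,
               proportion = run$model$variance_proportion,
               broken_stick = c(run$model$broken_stick,
                                rep(NA, length(run$model$eigenvalues) -
                                      length(run$model$broken_stick))),
               significant = run$model$significant),
    p("eigenvalues.tsv"))
  write_tsv_with_meta(
    data.frame(trait = rownames(run$correlations$r), run$correlations$r),
    p("correlations.tsv"))
  write_tsv_with_meta(run$axis_summary$means, p("group_axis_means.tsv"))
  write_tsv_with_meta(run$axis_summary$variances, p("group_axis_variances.tsv"))
  write_tsv_with_meta(run$volumes$table, p("group_volumes.tsv"))
  write_tsv_with_meta(run$volumes_trimmed$table, p("group_volumes_trimmed.tsv"))
  nm <- do.call(rbind, lapply(run$null_models, function(x)
    data.frame(model = x$model, n_reps = x$n_reps,
               observed_volume = x$observed_volume,
               mean_null_volume = mean(x$null_volumes),
               occupancy_percent = x$occupancy_percent, p_value = x$p_value)))
  write_tsv_with_meta(nm, p("nullmodel.tsv"), meta)
  rel <- do.call(rbind, lapply(c("pooled", "full", "omitted"), function(nmx) {
    pm <- run$relatedness[[nmx]]$permanova
    pd <- run$relatedness[[nmx]]$permdisp
    data.frame(analysis = nmx, permanova_df = pm$df_between,
               permanova_F = pm$pseudo_F, permanova_R2 = pm$R2,
               permanova_p = pm$p_value, permdisp_F = pd$F,
               permdisp_p = pd$p_value)
  }))
  write_tsv_with_meta(rel, p("relatedness.tsv"), meta)
  invisible(out_dir)
}

#' @export
print.traitspace_run <- function(x, ...) {
  cat("Trait-space pipeline run\n")
  print(x$model)
  cat(sprintf("Axes used: %d (hull geometry), %d (permutation tests)\n",
              x$n_axes_hull, x$n_axes_tests))
  cat(sprintf("Whole-assemblage hull volume: %.4f (trimmed: %.4f)\n",
              x$volumes$whole_volume, x$volumes_trimmed$whole_volume))
  for (m in names(x$null_models))
    cat(sprintf("  %-12s occupancy %6.2f%%  P = %.4g\n", m,
                x$null_models[[m]]$occupancy_percent,
                x$null_models[[m]]$p_value))
  print(x$relatedness)
  invisible(x)
}
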