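#' Permutational multivariate analysis of variance (one-way, Euclidean)
#'
#' Tests whether taxa are more dissimilar between taxonomic groups than
#' within them in the component-score space. Sums of squares are computed
#' from pairwise squared Euclidean distances: SS_total is the sum over all
#' pairs divided by n, SS_within the group-wise pair sums divided by the
#' group sizes, SS_between their difference. The pseudo-F statistic
#' (SS_between / df_between) / (SS_within / df_within) is referenced against
#' its distribution under random relabelling of taxa; the reported p-value
#' is (1 + #\{F_perm >= F_obs\}) / (n_perms + 1), so it is never exactly 0
#' and its minimum is 1 / (n_perms + 1).
#'
#' @param scores numeric taxa-by-axes matrix.
#' @param groups group label per taxon (at least 2 distinct labels, fewer
#'   labels than taxa).
#' @param n_perms number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return An object of class `permanova_result`: `pseudo_F`, `R2`
#'   (= SS_between / SS_total), `df_between`, `df_within`, `p_value`,
#'   `n_perms`, `ss` (the three sums of squares).
#' @export
permanova <- function(scores, groups, n_perms = 999L, seed = 1L) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  n <- nrow(scores)
  if (length(groups) != n) stop("'groups' must have one label per score row")
  glev <- unique(groups)
  a <- length(glev)
  if (a < 2) stop("need at least 2 groups")
  if (a >= n) stop("more groups than error degrees of freedom allow")
  if (n_perms < 1) stop("'n_perms' must be at least 1")
  d2 <- as.matrix(stats::dist(scores))^2
  ss_total <- sum(d2) / (2 * n)
  gidx <- split(seq_len(n), groups)
  ss_within_of <- function(idx_list) {
    sum(vapply(idx_list, function(idx)
      sum(d2[idx, idx]) / (2 * length(idx)), numeric(1)))
  }
  ss_within <- ss_within_of(gidx)
  ss_between <- ss_total - ss_within
  df_b <- a - 1L
  df_w <- n - a
  f_of <- function(ssw) ((ss_total - ssw) / df_b) / (ssw / df_w)
  f_obs <- f_of(ss_within)
  labels <- groups
  f_perm <- with_seed(seed, vapply(seq_len(n_perms), function(r) {
    f_of(ss_within_of(split(seq_len(n), labels[sample.int(n)])))
  }, numeric(1)))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perms + 1)
  structure(list(pseudo_F = f_obs, R2 = ss_between / ss_total,
                 df_between = df_b, df_within = df_w, p_value = p,
                 n_perms = as.integer(n_perms),
                 ss = c(between = ss_between, within = ss_within,
                        total = ss_total)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (Euclidean distance, one-way)\n")
  cat(sprintf("  pseudo-F = %.4g on %d and %d df,  R2 = %.3f,  P = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_between, x$df_within, x$R2, x$p_value, x$n_perms))
  invisible(x)
}

#' Geometric (spatial) median of a point set
#'
#' The point minimizing the summed Euclidean distances to the rows of
#' `points`, found by Weiszfeld iteration started at the centroid; iterates
#' that land on a data point are handled by clamping the distance weights.
#'
#' @param points numeric n-by-d matrix.
#' @param tol convergence tolerance on the iterate displacement.
#' @param max_iter iteration cap.
#' @return A length-d numeric vector.
#' @export
spatial_median <- function(points, tol = 1e-9, max_iter = 1000L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 1L) return(points[1L, ])
  y <- colMeans(points)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(points, 2L, y)^2))
    w <- 1 / pmax(d, 1e-12)
    y_new <- colSums(points * w) / sum(w)
    if (sqrt(sum((y_new - y)^2)) < tol) return(y_new)
    y <- y_new
  }
  y
}

#' Permutation test for homogeneity of multivariate dispersion
#'
#' Compares the within-group spread of taxa in the component-score space:
#' each taxon's dispersion is its Euclidean distance to the spatial
#' (geometric) median of its group, and the group mean distances are
#' compared by a one-way ANOVA F statistic. Significance is assessed by
#' permuting the group labels and recomputing the group medians, distances
#' and F for every permutation, so the reference distribution reflects the
#' full estimation procedure. A singleton group has dispersion 0 by
#' construction.
#'
#' @inheritParams permanova
#' @param center `"median"` (default, the spatial median) or `"centroid"`
#'   (per-axis mean) as the group centre the distances are measured from.
#' @return An object of class `permdisp_result`: `F`, `p_value`,
#'   `distances` (per-taxon distance to its group centre), `group_means`
#'   (per-group mean distance), `n_perms`, `df`, `center`.
#' @export
permdisp <- function(scores, groups, n_perms = 999L, seed = 1L,
                     center = c("median", "centroid")) {
  center <- match.arg(center)
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  n <- nrow(scores)
  if (length(groups) != n) stop("'groups' must have one label per score row")
  glev <- unique(groups)
  a <- length(glev)
  if (a < 2) stop("need at least 2 groups")
  if (a >= n) stop("more groups than error degrees of freedom allow")
  if (n_perms < 1) stop("'n_perms' must be at least 1")
  dist_to_center <- function(labels) {
    z <- numeric(n)
    for (g in unique(labels)) {
      rows <- which(labels == g)
      pts <- scores[rows, , drop = FALSE]
      ctr <- if (center == "median") spatial_median(pts) else colMeans(pts)
      z[rows] <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
    }
    z
  }
  anova_f <- function(z, labels) {
    gm <- tapply(z, labels, mean)
    ng <- tapply(z, labels, length)
    grand <- mean(z)
    ssb <- sum(ng * (gm - grand)^2)
    ssw <- sum((z - gm[labels])^2)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  z_obs <- dist_to_center(groups)
  f_obs <- anova_f(z_obs, groups)
  f_perm <- with_seed(seed, vapply(seq_len(n_perms), function(r) {
    lab <- groups[sample.int(n)]
    anova_f(dist_to_center(lab), lab)
  }, numeric(1)))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perms + 1)
  gm <- tapply(z_obs, groups, mean)
  structure(list(F = f_obs, p_value = p,
                 distances = stats::setNames(z_obs, rownames(scores)),
                 group_means = gm[glev], n_perms = as.integer(n_perms),
                 df = c(between = a - 1L, within = n - a), center = center),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat("PERMDISP (distance to group spatial median, Euclidean)\n")
  cat(sprintf("  F = %.4g on %d and %d df,  P = %.4g (%d permutations)\n",
              x$F, x$df["between"], x$df["within"], x$p_value, x$n_perms))
  cat("  mean distance to median by group:\n")
  gm <- sort(x$group_means, decreasing = TRUE)
  for (g in names(gm)) cat(sprintf("    %-20s %.3f\n", g, gm[g]))
  invisible(x)
}

#' Taxonomic-relatedness test suite
#'
#' Runs [permanova()] and [permdisp()] three ways to probe how the pooling
#' of small taxonomic groups affects the evidence for taxonomic constraint:
#' with the pooled labels (small groups aggregated into one category), with
#' the full fine-grained labels, and with the former pooled-category taxa
#' omitted entirely.
#'
#' @param scores numeric taxa-by-axes matrix.
#' @param groups_pooled labels with small groups pooled (e.g. into
#'   `"Others"`).
#' @param groups_full fine-grained labels for the same taxa.
#' @param others_label the pooled category's label in `groups_pooled`.
#' @param n_perms permutations per test.
#' @param seed integer seed.
#' @return A list of class `relatedness_suite` with elements `pooled`,
#'   `full`, `omitted`, each holding `$permanova` and `$permdisp` results,
#'   plus `n_omitted`.
#' @export
run_relatedness_suite <- function(scores, groups_pooled, groups_full,
                                  others_label = "Others", n_perms = 999L,
                                  seed = 1L) {
  scores <- as.matrix(scores)
  if (length(groups_pooled) != nrow(scores) ||
      length(groups_full) != nrow(scores))
    stop("label vectors must align with the score rows")
  keep <- groups_pooled != others_label
  one <- function(sc, g, stage) list(
    permanova = permanova(sc, g, n_perms, substream_seed(seed, paste0("pm_", stage))),
    permdisp = permdisp(sc, g, n_perms, substream_seed(seed, paste0("pd_", stage))))
  structure(list(
    pooled = one(scores, groups_pooled, "pooled"),
    full = one(scores, groups_full, "full"),
    omitted = one(scores[keep, , drop = FALSE], groups_full[keep], "omitted"),
    n_omitted = sum(!keep)),
    class = "relatedness_suite")
}

#' @export
print.relatedness_suite <- function(x, ...) {
  lab <- c(pooled = "pooled small groups", full = "full labels",
           omitted = "small groups omitted")
  for (nm in c("pooled", "full", "omitted")) {
    pm <- x[[nm]]$permanova
    pd <- x[[nm]]$permdisp
    cat(sprintf("%s:\n  PERMANOVA df = %d, R2 = %.2f, P = %.3f | PERMDISP F = %.3f, P = %.3f\n",
                lab[nm], pm$df_between, pm$R2, pm$p_value, pd$F, pd$p_value))
  }
  invisible(x)
}
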