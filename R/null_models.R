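#' Monte-Carlo null models of trait-space occupancy
#'
#' Tests whether an assemblage's occupied trait space (trimmed convex-hull
#' volume of its component scores) is smaller than expected if the ordination
#' axes varied independently. Three null models generate simulated score
#' clouds of the same size as the observed one:
#' \describe{
#'   \item{uniform}{each axis drawn independently from a uniform
#'     distribution over the observed per-axis range;}
#'   \item{normal}{each axis drawn independently from a normal distribution
#'     with the observed per-axis mean and standard deviation;}
#'   \item{permutation}{each axis's observed values independently shuffled,
#'     preserving every marginal distribution exactly while destroying
#'     inter-axis dependence.}
#' }
#' Axis ranges and moments come from the untrimmed observed scores; centroid
#' trimming (default: the 95% of points nearest the centroid) is applied to
#' the observed and to every simulated cloud alike before the hull is taken.
#' The occupancy percentage is 100 * observed volume / mean (or median) null
#' volume; a value well below 100 means the assemblage is concentrated in
#' trait space. The p-value is the one-sided Monte-Carlo estimate
#' (1 + #\{null <= observed\}) / (n_reps + 1), small when the observed hull
#' is smaller than essentially all simulated hulls; it is never exactly 0.
#'
#' @param scores numeric taxa-by-axes matrix of component scores (k >= 2).
#' @param model `"uniform"`, `"normal"` or `"permutation"`.
#' @param n_reps number of simulated clouds (default 999).
#' @param fraction centroid-trimming fraction passed to
#'   [trim_to_centroid_fraction()].
#' @param seed integer seed; same seed, same null volumes.
#' @param center `"mean"` or `"median"` of the null volumes as the occupancy
#'   denominator.
#' @return An object of class `null_model_result`: `model`, `n_reps`,
#'   `observed_volume`, `null_volumes`, `occupancy_percent`, `p_value`,
#'   `fraction`, `n_taxa`, `n_axes`.
#' @export
null_model_test <- function(scores, model = c("uniform", "normal", "permutation"),
                            n_reps = 999L, fraction = 0.95, seed = 1L,
                            center = c("mean", "median")) {
  model <- match.arg(model)
  center <- match.arg(center)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (k < 2) stop("need at least 2 score axes")
  if (n < k + 1) stop("need at least k+1 taxa for a k-dimensional hull")
  if (n_reps < 1) stop("'n_reps' must be at least 1")
  observed <- trimmed_hull_volume(scores, fraction)$volume
  lo <- apply(scores, 2L, min)
  hi <- apply(scores, 2L, max)
  mu <- colMeans(scores)
  sdv <- apply(scores, 2L, stats::sd)
  null_volumes <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    sim <- switch(model,
      uniform = vapply(seq_len(k), function(a) stats::runif(n, lo[a], hi[a]),
                       numeric(n)),
      normal = vapply(seq_len(k), function(a) stats::rnorm(n, mu[a], sdv[a]),
                      numeric(n)),
      permutation = vapply(seq_len(k), function(a) scores[sample.int(n), a],
                           numeric(n)))
    trimmed_hull_volume(sim, fraction)$volume
  }, numeric(1)))
  denom <- if (center == "mean") mean(null_volumes) else stats::median(null_volumes)
  occupancy <- if (denom > 0) 100 * observed / denom else NA_real_
  p <- (1 + sum(null_volumes <= observed)) / (n_reps + 1)
  structure(list(model = model, n_reps = as.integer(n_reps),
                 observed_volume = observed, null_volumes = null_volumes,
                 occupancy_percent = occupancy, p_value = p,
                 fraction = fraction, n_taxa = n, n_axes = k,
                 center = center, seed = as.integer(seed)),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("Trait-space occupancy null model: %s (%d reps)\n",
              x$model, x$n_reps))
  cat(sprintf("  observed volume (trim %.0f%%): %.4f\n",
              100 * x$fraction, x$observed_volume))
  cat(sprintf("  %s null volume: %.4f\n", x$center,
              if (x$center == "mean") mean(x$null_volumes)
              else stats::median(x$null_volumes)))
  cat(sprintf("  occupancy: %.2f%%   P = %.4g\n", x$occupancy_percent,
              x$p_value))
  invisible(x)
}
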