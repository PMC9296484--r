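#' Pairwise-deletion centred covariance of an incomplete matrix
#'
#' Computes the traits-by-traits covariance used by [ipca()]. Each variable
#' is centred on its available-case mean; the (j,k) entry is the sum of
#' cross-products over taxa where both traits are observed, divided by
#' (n_jk - 1) with n_jk the number of jointly observed rows. On complete
#' data this is exactly the textbook sample covariance. With missing cells
#' the matrix is symmetric by construction but need not be positive
#' semi-definite.
#'
#' @param x a `standardized_trait_table`, `fuzzy_trait_table`, or a numeric
#'   matrix with `NA` for missing cells.
#' @return A symmetric p-by-p matrix with attributes `means` (available-case
#'   column means) and `n_pairs` (jointly observed counts).
#' @export
pairwise_centred_covariance <- function(x) {
  x <- as_trait_matrix(x)
  obs <- !is.na(x)
  n_obs <- colSums(obs)
  if (any(n_obs < 2))
    stop("trait(s) with fewer than 2 observed values: ",
         paste(colnames(x)[n_obs < 2], collapse = ", "))
  means <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2L, means)
  xc[!obs] <- 0
  n_pair <- crossprod(obs * 1)
  if (any(n_pair < 2)) {
    bad <- which(n_pair < 2, arr.ind = TRUE)[1L, ]
    stop("trait pair with fewer than 2 jointly observed rows: ",
         colnames(x)[bad[1L]], " / ", colnames(x)[bad[2L]])
  }
  s <- crossprod(xc) / (n_pair - 1)
  s <- (s + t(s)) / 2
  attr(s, "means") <- means
  attr(s, "n_pairs") <- n_pair
  s
}

as_trait_matrix <- function(x) {
  if (inherits(x, c("standardized_trait_table", "fuzzy_trait_table"))) x$matrix * 1.0
  else if (is.matrix(x)) x * 1.0
  else stop("expected a trait table or a numeric matrix")
}

#' Centred principal component analysis of incomplete data
#'
#' Fits a centred (not variance-standardized) PCA that tolerates missing
#' cells: the covariance matrix is built by pairwise deletion
#' ([pairwise_centred_covariance()]) and eigendecomposed; negative
#' eigenvalues, which can arise because a pairwise matrix need not be
#' positive semi-definite, are clipped to zero and excluded from the
#' variance-proportion denominator. The score of a taxon on an axis is the
#' sum over its observed traits of (value - trait mean) times the trait's
#' loading; missing traits contribute zero. On complete data the fit
#' coincides with classical centred PCA. Variance standardization is
#' deliberately not offered here: for fuzzy-coded traits it would destroy
#' the relatedness of the trait states within a group (use
#' [standardize_by_group()] beforehand instead).
#'
#' Axis signs follow a fixed convention — the largest-magnitude loading of
#' each axis is positive — so fitted objects are reproducible.
#'
#' @param table a `standardized_trait_table` (recommended), a
#'   `fuzzy_trait_table`, or a numeric matrix with `NA` for missing cells.
#' @param rescale_scores if `TRUE`, each taxon's scores are multiplied by
#'   p / p_observed (its fraction of observed traits inverted), a
#'   sensitivity-analysis variant compensating for the dropped terms of
#'   incomplete rows. Default `FALSE`.
#' @return An object of class `ipca` with elements `means`, `eigenvalues`
#'   (non-increasing, clipped at zero), `loadings` (traits x axes,
#'   orthonormal columns), `scores` (taxa x axes), `variance_proportion`,
#'   `n_variables`, `n_taxa`, `n_positive` (axes with positive eigenvalue),
#'   `broken_stick`, `retained` (leading axes whose variance proportion
#'   exceeds the broken-stick expectation, see [select_axes()]), `taxa`
#'   (metadata data frame or `NULL`), and `complete` (had the input no
#'   missing cells?).
#' @seealso [select_axes()], [trait_axis_correlations()], [predict.ipca()]
#' @export
ipca <- function(table, rescale_scores = FALSE) {
  x <- as_trait_matrix(table)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  s <- pairwise_centred_covariance(x)
  means <- attr(s, "means")
  eig <- eigen(s, symmetric = TRUE)
  ev <- eig$values
  ev[ev < max(ev) * 1e-12] <- 0  # clip negatives and numerical dust
  load <- eig$vectors
  # sign convention: largest-|loading| entry of each axis is positive
  for (a in seq_len(ncol(load))) {
    peak <- which.max(abs(load[, a]))
    if (load[peak, a] < 0) load[, a] <- -load[, a]
  }
  dimnames(load) <- list(colnames(x), paste0("Axis", seq_len(ncol(load))))
  obs <- !is.na(x)
  xc <- sweep(x, 2L, means)
  xc[!obs] <- 0
  scores <- xc %*% load
  if (rescale_scores) {
    p_obs <- rowSums(obs)
    if (any(p_obs == 0)) stop("taxon with no observed traits cannot be scored")
    scores <- scores * (ncol(x) / p_obs)
  }
  rownames(scores) <- rownames(x)
  n_pos <- sum(ev > 0)
  vp <- rep(0, length(ev))
  if (n_pos > 0) vp[ev > 0] <- ev[ev > 0] / sum(ev[ev > 0])
  model <- structure(list(
    means = means, eigenvalues = ev, loadings = load, scores = scores,
    variance_proportion = vp, n_variables = ncol(x), n_taxa = nrow(x),
    n_positive = n_pos,
    taxa = if (inherits(table, c("standardized_trait_table", "fuzzy_trait_table")))
      table$taxa else NULL,
    complete = all(obs), rescaled = rescale_scores,
    call = match.call()), class = "ipca")
  sel <- select_axes(model)
  model$broken_stick <- sel$broken_stick
  model$retained <- sel$retained
  model$significant <- sel$significant
  model
}

#' Broken-stick eigenvalue proportions
#'
#' Expected proportions of total variance under the broken-stick null model:
#' a unit stick broken at p - 1 uniform random points, pieces sorted by
#' size. The k-th largest piece has expectation b_k = (1/p) * sum_{i=k}^p
#' 1/i. Proportions sum to one and decrease strictly in k.
#'
#' @param p number of axes (positive integer).
#' @return Numeric vector of length `p`.
#' @export
broken_stick_proportions <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 1 || p != round(p))
    stop("'p' must be a positive integer")
  rev(cumsum(rev(1 / seq_len(p)))) / p
}

#' Broken-stick axis selection
#'
#' Flags axis k significant when its observed variance proportion exceeds
#' the broken-stick expectation b_k, and retains the leading run of
#' consecutive significant axes (stopping at the first failure). Only axes
#' with positive eigenvalue are eligible.
#'
#' @param model an [ipca()] fit.
#' @return A list of class `axis_selection`: `broken_stick` (expected
#'   proportions over the positive axes), `significant` (logical per axis),
#'   `retained` (count of leading significant axes).
#' @export
select_axes <- function(model) {
  stopifnot(inherits(model, "ipca"))
  p <- model$n_positive
  sig <- rep(FALSE, length(model$eigenvalues))
  bs <- numeric(0)
  if (p >= 1) {
    bs <- broken_stick_proportions(p)
    sig[seq_len(p)] <- model$variance_proportion[seq_len(p)] > bs
  }
  first_fail <- match(FALSE, sig)
  retained <- if (is.na(first_fail)) length(sig) else first_fail - 1L
  structure(list(broken_stick = bs, significant = sig,
                 retained = as.integer(retained)),
            class = "axis_selection")
}

#' Trait-axis correlation screening
#'
#' Pearson correlations between each trait (available cases only) and the
#' component scores, used to decide which traits contribute to which
#' ordination axis; traits with |r| above the threshold (default 0.5) are
#' retained for interpretation.
#'
#' @param table the trait table the model was fitted to.
#' @param model an [ipca()] fit.
#' @param n_axes number of leading axes to screen (default: the
#'   broken-stick-retained axes, or 1 if none were retained).
#' @param threshold retention threshold on |r|.
#' @return A list of class `trait_axis_correlation`: `r` (traits x axes),
#'   `retained` (per axis, the trait abbreviations with |r| > threshold),
#'   `zero_variance` (traits whose r is undefined, reported as 0 with a
#'   warning), `threshold`.
#' @export
trait_axis_correlations <- function(table, model, n_axes = NULL, threshold = 0.5) {
  stopifnot(inherits(model, "ipca"))
  x <- as_trait_matrix(table)
  if (is.null(n_axes)) n_axes <- max(model$retained, 1L)
  if (n_axes > ncol(model$scores))
    stop("'n_axes' exceeds the number of axes in the model")
  axes <- seq_len(n_axes)
  r <- matrix(NA_real_, ncol(x), n_axes,
              dimnames = list(colnames(x), colnames(model$scores)[axes]))
  zero_var <- rep(FALSE, ncol(x))
  for (j in seq_len(ncol(x))) {
    rows <- which(!is.na(x[, j]))
    if (length(rows) < 2 || stats::sd(x[rows, j]) == 0) {
      zero_var[j] <- TRUE
      r[j, ] <- 0
    } else {
      for (a in axes) {
        sa <- stats::sd(model$scores[rows, a])
        r[j, a] <- if (sa == 0) 0 else
          stats::cor(x[rows, j], model$scores[rows, a])
      }
    }
  }
  if (any(zero_var))
    warning("zero-variance trait(s), correlation reported as 0: ",
            paste(colnames(x)[zero_var], collapse = ", "))
  retained <- lapply(axes, function(a) rownames(r)[abs(r[, a]) > threshold])
  names(retained) <- colnames(r)
  structure(list(r = r, retained = retained, zero_variance = zero_var,
                 threshold = threshold),
            class = "trait_axis_correlation")
}

#' @export
print.ipca <- function(x, ...) {
  cat("Centred PCA of incomplete data\n")
  cat(sprintf("  %d taxa x %d traits (%s)\n", x$n_taxa, x$n_variables,
              if (x$complete) "complete" else "incomplete"))
  cat(sprintf("  %d axes with positive eigenvalue; %d broken-stick-significant\n",
              x$n_positive, x$retained))
  k <- min(4L, x$n_positive)
  if (k > 0)
    cat("  Variance explained (first axes): ",
        paste(sprintf("%.1f%%", 100 * x$variance_proportion[seq_len(k)]),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ipca <- function(object, n_axes = NULL, ...) {
  p <- object$n_positive
  if (is.null(n_axes)) n_axes <- p
  n_axes <- min(n_axes, p)
  bs <- object$broken_stick
  tab <- data.frame(
    axis = seq_len(n_axes),
    eigenvalue = object$eigenvalues[seq_len(n_axes)],
    proportion = object$variance_proportion[seq_len(n_axes)],
    cumulative = cumsum(object$variance_proportion)[seq_len(n_axes)],
    broken_stick = bs[seq_len(n_axes)],
    significant = object$significant[seq_len(n_axes)])
  structure(list(table = tab, retained = object$retained,
                 n_taxa = object$n_taxa, n_variables = object$n_variables),
            class = "summary.ipca")
}

#' @export
print.summary.ipca <- function(x, ...) {
  cat(sprintf("Centred PCA of incomplete data: %d taxa x %d traits\n",
              x$n_taxa, x$n_variables))
  tab <- x$table
  tab$eigenvalue <- signif(tab$eigenvalue, 4)
  tab$proportion <- sprintf("%.3f", tab$proportion)
  tab$cumulative <- sprintf("%.3f", tab$cumulative)
  tab$broken_stick <- sprintf("%.3f", tab$broken_stick)
  print(tab, row.names = FALSE)
  cat("Retained (broken-stick):", x$retained, "axes\n")
  invisible(x)
}

#' Scores for new taxa from a fitted incomplete PCA
#'
#' Projects new rows onto the fitted axes using the training means and
#' loadings; missing cells contribute zero, as in fitting.
#'
#' @param object an [ipca()] fit.
#' @param newdata a trait table or numeric matrix with the same traits.
#' @param ... unused.
#' @return A taxa-by-axes score matrix.
#' @export
predict.ipca <- function(object, newdata, ...) {
  x <- as_trait_matrix(newdata)
  if (ncol(x) != object$n_variables)
    stop("newdata has ", ncol(x), " traits; model expects ", object$n_variables)
  xc <- sweep(x, 2L, object$means)
  xc[is.na(xc)] <- 0
  out <- xc %*% object$loadings
  if (isTRUE(object$rescaled)) {
    p_obs <- rowSums(!is.na(x))
    out <- out * (ncol(x) / p_obs)
  }
  out
}

#' @export
screeplot.ipca <- function(x, n_axes = NULL, ...) {
  p <- x$n_positive
  if (is.null(n_axes)) n_axes <- p
  n_axes <- min(n_axes, p)
  vp <- x$variance_proportion[seq_len(n_axes)]
  bs <- x$broken_stick[seq_len(n_axes)]
  graphics::barplot(vp, names.arg = seq_len(n_axes),
                    xlab = "Axis", ylab = "Variance proportion", ...)
  graphics::lines(seq_len(n_axes) * 1.2 - 0.5, bs, type = "b", pch = 19)
  invisible(x)
}

#' @export
plot.ipca <- function(x, axes = c(1L, 2L), ...) {
  sc <- x$scores[, axes, drop = FALSE]
  grp <- if (!is.null(x$taxa)) factor(x$taxa$group) else factor(rep(1, nrow(sc)))
  graphics::plot(sc[, 1L], sc[, 2L], col = as.integer(grp), pch = 16,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1L],
                                100 * x$variance_proportion[axes[1L]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2L],
                                100 * x$variance_proportion[axes[2L]]), ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  invisible(x)
}
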