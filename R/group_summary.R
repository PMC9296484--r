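#' Per-group position and spread along ordination axes
#'
#' Summarizes where each taxonomic group sits in the trait space (per-axis
#' arithmetic mean of its component scores) and how variable it is there
#' (per-axis sample variance, n - 1 divisor). Groups far from the origin
#' contribute distinct trait syndromes; groups with large variance are
#' functionally heterogeneous. Singleton groups get variance 0 and are
#' flagged.
#'
#' @param scores numeric taxa-by-axes matrix.
#' @param groups group label per taxon.
#' @param n_axes number of leading axes to summarize (default 4).
#' @return An object of class `group_axis_summary`: data frames `means` and
#'   `variances` (one row per group, one column per axis, plus `n_taxa`),
#'   and `singleton` flags.
#' @export
group_axis_summary <- function(scores, groups, n_axes = 4L) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  if (length(groups) != nrow(scores))
    stop("'groups' must have one label per score row")
  if (n_axes > ncol(scores))
    stop("'n_axes' exceeds the available axes")
  sc <- scores[, seq_len(n_axes), drop = FALSE]
  glev <- unique(groups)
  mns <- vars <- matrix(NA_real_, length(glev), n_axes,
                        dimnames = list(glev, colnames(sc)))
  n_g <- integer(length(glev))
  for (i in seq_along(glev)) {
    rows <- groups == glev[i]
    n_g[i] <- sum(rows)
    mns[i, ] <- colMeans(sc[rows, , drop = FALSE])
    vars[i, ] <- if (n_g[i] > 1) apply(sc[rows, , drop = FALSE], 2L, stats::var)
                 else rep(0, n_axes)
  }
  structure(list(
    means = data.frame(group = glev, mns, n_taxa = n_g, check.names = FALSE,
                       row.names = NULL),
    variances = data.frame(group = glev, vars, n_taxa = n_g,
                           check.names = FALSE, row.names = NULL),
    singleton = stats::setNames(n_g == 1L, glev)),
    class = "group_axis_summary")
}

#' @export
print.group_axis_summary <- function(x, digits = 2, ...) {
  cat("Group positions (axis means):\n")
  print(format(x$means, digits = digits), row.names = FALSE)
  cat("Group spread (axis variances):\n")
  print(format(x$variances, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Standardized trait-space volume
#'
#' Amount of trait space per taxon: 100 * volume / n_taxa. Dividing a
#' group's hull volume by its taxon count makes groups of different richness
#' comparable.
#'
#' @param volume hull volume(s).
#' @param n_taxa taxon count(s).
#' @return `100 * volume / n_taxa`.
#' @export
standardized_volume_percent <- function(volume, n_taxa) {
  if (any(n_taxa < 1)) stop("'n_taxa' must be positive")
  100 * volume / n_taxa
}

#' Expected proportional group volume
#'
#' The volume each group would occupy if the assemblage's trait space were
#' split evenly among the groups: whole-assemblage volume divided by the
#' number of groups. Group volumes below this value indicate functionally
#' distinct (non-overlapping) groups.
#'
#' @param whole_volume hull volume of the entire assemblage.
#' @param n_groups number of taxonomic groups.
#' @return `whole_volume / n_groups`.
#' @export
expected_proportional_volume <- function(whole_volume, n_groups) {
  if (n_groups < 1) stop("'n_groups' must be positive")
  whole_volume / n_groups
}

#' Trait-space volumes of taxonomic groups
#'
#' Convex-hull volume of the whole assemblage and of every taxonomic group
#' on the retained ordination axes, with the standardized (per-taxon) volume
#' and the expected proportional per-group volume. Groups too small or too
#' flat to span the k-dimensional space get volume 0 (degenerate).
#'
#' @param scores numeric taxa-by-axes matrix (all axes used).
#' @param groups group label per taxon.
#' @param trim if `TRUE`, each hull (whole and per group) is computed on the
#'   `fraction` of its points nearest its own centroid; the default `FALSE`
#'   uses every point.
#' @param fraction trimming fraction when `trim = TRUE`.
#' @return An object of class `group_volumes`: `table` (data frame with
#'   columns `group`, `n_taxa`, `volume`, `standardized_percent`,
#'   `degenerate`; first row is the whole assemblage),
#'   `expected_proportional` (whole volume / number of groups),
#'   `whole_volume`, `n_groups`.
#' @export
group_volumes <- function(scores, groups, trim = FALSE, fraction = 0.95) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  if (length(groups) != nrow(scores))
    stop("'groups' must have one label per score row")
  vol_of <- function(pts) {
    if (trim) trimmed_hull_volume(pts, fraction) else convex_hull_volume(pts)
  }
  whole <- vol_of(scores)
  glev <- unique(groups)
  rows <- lapply(glev, function(g) {
    pts <- scores[groups == g, , drop = FALSE]
    h <- vol_of(pts)
    data.frame(group = g, n_taxa = nrow(pts), volume = h$volume,
               standardized_percent = standardized_volume_percent(h$volume, nrow(pts)),
               degenerate = h$degenerate, stringsAsFactors = FALSE)
  })
  tab <- rbind(
    data.frame(group = "(whole assemblage)", n_taxa = nrow(scores),
               volume = whole$volume,
               standardized_percent = standardized_volume_percent(whole$volume,
                                                                  nrow(scores)),
               degenerate = whole$degenerate, stringsAsFactors = FALSE),
    do.call(rbind, rows))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 expected_proportional =
                   expected_proportional_volume(whole$volume, length(glev)),
                 whole_volume = whole$volume, n_groups = length(glev),
                 trim = trim, fraction = if (trim) fraction else NA_real_),
            class = "group_volumes")
}

#' @export
print.group_volumes <- function(x, ...) {
  cat(sprintf("Trait-space volumes on %s scores (%d groups):\n",
              if (x$trim) sprintf("trimmed (%.0f%%)", 100 * x$fraction)
              else "untrimmed", x$n_groups))
  tab <- x$table
  tab$volume <- signif(tab$volume, 4)
  tab$standardized_percent <- signif(tab$standardized_percent, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Expected proportional group volume: %.4g\n",
              x$expected_proportional))
  invisible(x)
}
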