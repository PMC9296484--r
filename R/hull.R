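#' Convex hull volume of a point cloud
#'
#' Exact d-dimensional volume of the convex hull of a set of points, the
#' occupancy statistic of functional trait-space analysis: with each taxon a
#' point in ordination space, the hull volume measures how much trait space
#' the assemblage fills. Degenerate configurations — fewer than d+1 points,
#' or points confined to a lower-dimensional affine subspace — return volume
#' 0 with a degeneracy flag rather than an error, mirroring how tiny
#' taxonomic groups occupy no measurable d-volume.
#'
#' @param points a numeric n-by-d matrix (rows = points); row names, if
#'   present, identify the points in the result.
#' @param joggle amplitude (relative to the coordinate scale) of the
#'   deterministic perturbation applied inside the hull engine to resolve
#'   ties and coplanarities; the induced volume error is of order
#'   `joggle` times the hull surface area. Set 0 to disable.
#' @return An object of class `hull_result`: `dimension`, `volume`,
#'   `vertices` (row indices on the hull), `vertex_ids` (row names, if any),
#'   `n_points_used`, `trimmed` (always `FALSE` here; see
#'   [trim_to_centroid_fraction()]), `degenerate`.
#' @examples
#' square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' convex_hull_volume(square)$volume  # 1
#' @export
convex_hull_volume <- function(points, joggle = 1e-8) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("non-finite coordinates in 'points'")
  n <- nrow(points)
  d <- ncol(points)
  if (n < 1 || d < 1) stop("'points' must have at least one row and column")
  res <- list(dimension = d, n_points_used = n, trimmed = FALSE)
  degenerate <- function() {
    structure(c(res, list(volume = 0, vertices = integer(0),
                          vertex_ids = character(0), degenerate = TRUE)),
              class = "hull_result")
  }
  if (n <= d) return(degenerate())
  if (d == 1L) {
    lo <- which.min(points[, 1L])
    hi <- which.max(points[, 1L])
    vol <- points[hi, 1L] - points[lo, 1L]
    if (vol <= 0) return(degenerate())
    verts <- sort(c(lo, hi))
    return(structure(c(res, list(volume = vol, vertices = verts,
                                 vertex_ids = rownames(points)[verts],
                                 degenerate = FALSE)),
                     class = "hull_result"))
  }
  # affine-rank screen: points on a lower-dimensional flat have zero d-volume
  ctr <- sweep(points, 2L, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[1L] == 0 || sv[d] < sv[1L] * 1e-10) return(degenerate())
  out <- .quickhull_cpp(points, joggle)
  if (isTRUE(out$degenerate)) return(degenerate())
  verts <- sort(out$vertices)
  structure(c(res, list(volume = out$volume, vertices = verts,
                        vertex_ids = rownames(points)[verts],
                        degenerate = FALSE)),
            class = "hull_result")
}

#' @export
print.hull_result <- function(x, ...) {
  cat(sprintf("Convex hull in %dD: volume %.6g (%d of %d points on the hull%s%s)\n",
              x$dimension, x$volume, length(x$vertices), x$n_points_used,
              if (x$trimmed) ", trimmed" else "",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Trim a point cloud to the fraction nearest its centroid
#'
#' Keeps the `floor(fraction * n)` points with the smallest Euclidean
#' distance to the centroid (the per-axis mean), discarding outlying points
#' before a hull computation so that single extreme taxa do not inflate the
#' measured trait-space volume. Ties in distance are broken by input order.
#'
#' @param points a numeric n-by-d matrix.
#' @param fraction in (0, 1\]; 1 keeps every point.
#' @return The retained rows, input order preserved, with the integer
#'   indices of the kept rows in `attr(, "kept")`.
#' @export
trim_to_centroid_fraction <- function(points, fraction = 0.95) {
  points <- as.matrix(points)
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0,1]")
  n <- nrow(points)
  keep_n <- floor(fraction * n)
  if (keep_n >= n) {
    out <- points
    attr(out, "kept") <- seq_len(n)
    return(out)
  }
  ctr <- colMeans(points)
  dist2 <- rowSums(sweep(points, 2L, ctr)^2)
  kept <- sort(order(dist2)[seq_len(keep_n)])  # order() is stable: ties by input order
  out <- points[kept, , drop = FALSE]
  attr(out, "kept") <- kept
  out
}

#' Trimmed hull volume
#'
#' Convenience wrapper: [trim_to_centroid_fraction()] then
#' [convex_hull_volume()], flagged as trimmed.
#'
#' @inheritParams convex_hull_volume
#' @inheritParams trim_to_centroid_fraction
#' @return A `hull_result` with `trimmed = TRUE` when `fraction < 1`.
#' @export
trimmed_hull_volume <- function(points, fraction = 0.95, joggle = 1e-8) {
  kept <- trim_to_centroid_fraction(points, fraction)
  h <- convex_hull_volume(kept, joggle)
  h$trimmed <- fraction < 1
  if (!is.null(attr(kept, "kept")))
    h$vertices <- attr(kept, "kept")[h$vertices]
  h
}
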