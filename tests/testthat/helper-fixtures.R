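# shared fixtures and independent oracles, built in code

# a two-group, five-trait dictionary for small hand-checkable tables
tiny_dictionary <- function() {
  trait_dictionary(list(
    list(name = "Feeding", max_code = 3,
         traits = data.frame(name = c("Grazer", "Predator", "Shredder"),
                             abbr = c("G1", "G2", "G3"))),
    list(name = "Size", max_code = 5,
         traits = data.frame(name = c("Small", "Large"),
                             abbr = c("S1", "S2")))))
}

tiny_table <- function(values = NULL, groups = c("A", "A", "B", "B")) {
  d <- tiny_dictionary()
  if (is.null(values))
    values <- matrix(c(3, 0, 1, 0, 5,
                       2, 1, 0, 1, 4,
                       0, 3, 0, 5, 0,
                       1, 2, 1, 4, 1), 4, 5, byrow = TRUE)
  fuzzy_trait_table(values,
                    data.frame(taxon = paste0("tx", seq_len(nrow(values))),
                               group = groups),
                    d)
}

# naive double-loop pairwise-deletion covariance: the oracle for the fast one
naive_pairwise_cov <- function(x) {
  p <- ncol(x)
  means <- colMeans(x, na.rm = TRUE)
  s <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    rows <- which(!is.na(x[, j]) & !is.na(x[, k]))
    s[j, k] <- sum((x[rows, j] - means[j]) * (x[rows, k] - means[k])) /
      (length(rows) - 1)
  }
  s
}

# brute-force one-way PERMANOVA sums of squares from the definition
naive_permanova_ss <- function(scores, groups) {
  n <- nrow(scores)
  d <- as.matrix(dist(scores))
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b) ss_within <- ss_within + d[idx[a], idx[b]]^2 / length(idx)
  }
  list(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

# exact point-in-hull test by brute-force facet enumeration (3D only):
# every triple of points whose plane has all points on one side is a facet
# supporting halfspace; a query point is inside iff it satisfies them all
brute_force_inhull_3d <- function(pts, queries, tol = 1e-9) {
  n <- nrow(pts)
  planes <- list()
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    a <- pts[trip[1], ]; b <- pts[trip[2], ]; c <- pts[trip[3], ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    nl <- sqrt(sum(nrm^2))
    if (nl < 1e-12) next
    nrm <- nrm / nl
    s <- pts %*% nrm - sum(nrm * a)
    if (all(s <= tol)) planes[[length(planes) + 1]] <- c(nrm, sum(nrm * a))
    else if (all(s >= -tol)) planes[[length(planes) + 1]] <- c(-nrm, -sum(nrm * a))
  }
  pl <- do.call(rbind, planes)
  inside <- rep(TRUE, nrow(queries))
  s <- queries %*% t(pl[, 1:3, drop = FALSE])
  for (f in seq_len(nrow(pl))) inside <- inside & (s[, f] <= pl[f, 4] + tol)
  inside
}

# align the sign of each oracle axis to the package convention before
# comparing loadings/scores
align_signs <- function(loadings, scores) {
  for (a in seq_len(ncol(loadings))) {
    peak <- which.max(abs(loadings[, a]))
    if (loadings[peak, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  list(loadings = loadings, scores = scores)
}
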