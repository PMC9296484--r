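test_that("pairwise covariance matches hand arithmetic and the naive oracle", {
  # two points (0,0) and (1,1): every entry 0.5
  expect_equal(unname(pairwise_centred_covariance(rbind(c(0, 0), c(1, 1)))),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  # a constant column gives a zero row/column
  x <- cbind(a = c(1, 1, 1), b = c(0, 1, 2))
  s <- pairwise_centred_covariance(x)
  expect_equal(unname(s[1, ]), c(0, 0))
  # complete data: equals the textbook covariance
  set.seed(21)
  y <- matrix(rnorm(60), 12, 5)
  expect_equal(unname(pairwise_centred_covariance(y)), unname(cov(y)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # incomplete data: matches the double-loop definition
  y[sample(length(y), 8)] <- NA
  expect_equal(unname(pairwise_centred_covariance(y)), naive_pairwise_cov(y),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a pair with <2 joint observations is refused by name
  z <- cbind(p = c(1, 2, NA, NA), q = c(NA, NA, 1, 2), r = 1:4)
  expect_error(pairwise_centred_covariance(z),
               "fewer than 2 jointly observed rows: [pq] / [pq]")
})

test_that("on complete data the incomplete PCA equals classical centred PCA", {
  set.seed(31)
  for (rep in 1:5) {
    x <- matrix(rnorm(50 * 10), 50, 10) %*% diag(sqrt(seq(0.2, 2, length = 10)))
    fit <- ipca(x)
    oracle <- prcomp(x, center = TRUE, scale. = FALSE)
    ev_oracle <- oracle$sdev^2
    expect_equal(fit$eigenvalues, ev_oracle, tolerance = 1e-8)
    al <- align_signs(oracle$rotation, oracle$x)
    expect_equal(unname(fit$loadings), unname(al$loadings), tolerance = 1e-6)
    expect_equal(unname(fit$scores), unname(al$scores), tolerance = 1e-6)
    # centred scores and total-variance conservation
    expect_true(all(abs(colMeans(fit$scores)) < 1e-6))
    expect_equal(sum(fit$eigenvalues), sum(diag(cov(x))), tolerance = 1e-10)
  }
})

test_that("degenerate geometry is handled: collinear points, rank-1 masking", {
  # points on the line y = x: one positive axis along (1,1)/sqrt(2)
  x <- cbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3))
  fit <- ipca(x)
  expect_equal(fit$eigenvalues[2], 0)
  expect_equal(unname(fit$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  # one masked cell in an otherwise rank-1 4x2 table: the leading axis
  # still carries nearly all variance
  xm <- x
  xm[2, 2] <- NA
  fitm <- ipca(xm)
  expect_gt(fitm$variance_proportion[1], 0.9)
})

test_that("broken-stick proportions match the closed form and a simulation", {
  expect_equal(broken_stick_proportions(2), c(0.75, 0.25))
  expect_equal(broken_stick_proportions(1), 1)
  expect_error(broken_stick_proportions(0), "positive")
  for (p in c(3, 17, 63, 500, 10000)) {
    b <- broken_stick_proportions(p)
    expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_true(all(diff(b) < 0))
  }
  # simulation oracle: largest piece of a unit stick broken at 62 uniform
  # points (simulated via normalized exponential spacings)
  p <- 63
  set.seed(7)
  n_sim <- 1e6
  chunk <- 1e5
  tot <- 0
  for (i in seq_len(n_sim / chunk)) {
    e <- matrix(rexp(chunk * p), chunk, p)
    tot <- tot + sum(apply(e / rowSums(e), 1, max))
  }
  b1_sim <- tot / n_sim
  # MC standard error of the max piece (its sd is below its mean b1)
  se <- broken_stick_proportions(p)[1] / sqrt(n_sim)
  expect_lt(abs(b1_sim - broken_stick_proportions(p)[1]), 3 * se)
})

test_that("axis retention stops at the first broken-stick failure", {
  fake <- structure(list(
    eigenvalues = c(0.8, 0.2), variance_proportion = c(0.8, 0.2),
    n_positive = 2L), class = "ipca")
  expect_equal(select_axes(fake)$retained, 1L)
  # all proportions equal 1/p: nothing beats the first stick
  flat <- structure(list(
    eigenvalues = rep(1, 5), variance_proportion = rep(0.2, 5),
    n_positive = 5L), class = "ipca")
  expect_equal(select_axes(flat)$retained, 0L)
  # later axes exceeding their stick do not rescue a failed first axis
  mid <- structure(list(
    eigenvalues = c(0.5, 0.3, 0.2), variance_proportion = c(0.5, 0.3, 0.2),
    n_positive = 3L), class = "ipca")
  expect_equal(select_axes(mid)$significant, c(FALSE, TRUE, TRUE))
  expect_equal(select_axes(mid)$retained, 0L)
})

test_that("trait-axis correlations match cor() and honor the threshold", {
  set.seed(41)
  x <- matrix(rnorm(30 * 6), 30, 6)
  colnames(x) <- paste0("T", 1:6)
  fit <- ipca(x)
  ta <- trait_axis_correlations(x, fit, n_axes = 3)
  for (j in 1:6) for (a in 1:3)
    expect_equal(ta$r[j, a], cor(x[, j], fit$scores[, a]), tolerance = 1e-10)
  # with orthogonal centred columns the axes are the variables themselves,
  # so the dominant trait correlates perfectly with axis 1
  x2 <- cbind(main = c(-3, -1, 1, 3), minor = 0.1 * c(1, -1, -1, 1))
  fit2 <- ipca(x2)
  ta2 <- trait_axis_correlations(x2, fit2, n_axes = 1)
  expect_equal(unname(ta2$r["main", 1]), 1, tolerance = 1e-10)
  # an impossible threshold empties every retained list
  none <- trait_axis_correlations(x, fit, n_axes = 3, threshold = 1.01)
  expect_true(all(lengths(none$retained) == 0))
  # zero-variance traits are flagged and set to 0
  xz <- cbind(x, flat = rep(1, 30))
  fitz <- ipca(xz)
  expect_warning(taz <- trait_axis_correlations(xz, fitz, n_axes = 2),
                 "zero-variance")
  expect_equal(unname(taz$r["flat", ]), c(0, 0))
})

test_that("light masking perturbs the leading eigenvalue only slightly", {
  cfg <- synthetic_config(seed = 17)
  tab <- simulate_fuzzy_table(cfg)
  std <- standardize_by_group(tab)
  full <- ipca(std)
  masked <- inject_missingness(tab, 0.01, 77)
  part <- ipca(standardize_by_group(masked))
  expect_lt(abs(part$eigenvalues[1] - full$eigenvalues[1]) / full$eigenvalues[1],
            0.05)
})

test_that("prediction reproduces training scores and handles new rows", {
  set.seed(51)
  x <- matrix(rnorm(40 * 5), 40, 5)
  fit <- ipca(x)
  expect_equal(predict(fit, x), fit$scores, ignore_attr = TRUE)
  new <- matrix(rnorm(10), 2, 5)
  pr <- predict(fit, new)
  expect_equal(dim(pr), c(2L, 5L))
  expect_equal(pr, sweep(new, 2, fit$means) %*% fit$loadings,
               ignore_attr = TRUE)
})
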