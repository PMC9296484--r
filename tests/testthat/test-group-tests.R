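test_that("PERMANOVA sums of squares match the brute-force definition and vegan", {
  set.seed(71)
  sc <- matrix(rnorm(30 * 4), 30, 4)
  grp <- rep(c("A", "B", "C"), each = 10)
  pm <- permanova(sc, grp, n_perms = 99, seed = 1)
  oracle <- naive_permanova_ss(sc, grp)
  expect_equal(pm$ss[["total"]], oracle$total, tolerance = 1e-10)
  expect_equal(pm$ss[["within"]], oracle$within, tolerance = 1e-10)
  f_oracle <- (oracle$between / 2) / (oracle$within / 27)
  expect_equal(pm$pseudo_F, f_oracle, tolerance = 1e-10)
  expect_equal(pm$R2, oracle$between / oracle$total, tolerance = 1e-10)
  expect_equal(pm$df_between, 2L)
  expect_equal(pm$df_within, 27L)
  # vegan cross-check of the observed statistic
  ad <- vegan::adonis2(dist(sc) ~ grp, data = data.frame(grp = grp),
                       permutations = 2)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-8)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-8)
})

test_that("PERMANOVA edge geometry: coincident clouds and complete separation", {
  pts <- matrix(rnorm(20, sd = 1), 10, 2)
  dup <- rbind(pts, pts)  # the two groups are the same cloud
  pm0 <- permanova(dup, rep(c("A", "B"), each = 10), n_perms = 99, seed = 2)
  expect_lt(pm0$ss[["between"]], 1e-10)
  expect_lt(pm0$pseudo_F, 1e-10)
  expect_gt(pm0$p_value, 0.9)
  expect_lt(abs(pm0$R2), 1e-10)
  # complete separation: no permutation reaches the observed F
  far <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 100, 0.1), 10, 2))
  pm1 <- permanova(far, rep(c("A", "B"), each = 10), n_perms = 99, seed = 3)
  expect_equal(pm1$p_value, 0.01)
  expect_error(permanova(pts, rep("A", 10)), "at least 2 groups")
  expect_error(permanova(pts[1:3, ], c("A", "B", "C")), "more groups")
})

test_that("PERMANOVA p-values are calibrated under exchangeable labels", {
  set.seed(72)
  rej <- vapply(1:200, function(r) {
    sc <- matrix(rnorm(30 * 3), 30, 3)
    grp <- sample(rep(c("A", "B", "C"), each = 10))
    permanova(sc, grp, n_perms = 99, seed = 5000 + r)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("the spatial median minimizes summed distances and stays in the hull", {
  set.seed(73)
  pts <- matrix(rnorm(25 * 3), 25, 3)
  med <- spatial_median(pts)
  f <- function(y) sum(sqrt(rowSums(sweep(pts, 2, y)^2)))
  # no small perturbation improves the objective
  for (r in 1:20) {
    expect_gte(f(med + rnorm(3, 0, 1e-4)), f(med) - 1e-10)
  }
  # the optimum found by a general-purpose optimizer agrees
  opt <- optim(colMeans(pts), f, method = "BFGS")
  expect_equal(f(med), opt$value, tolerance = 1e-8)
  # hull membership: adding the median cannot grow the hull
  v0 <- convex_hull_volume(pts)$volume
  v1 <- convex_hull_volume(rbind(pts, med))$volume
  expect_equal(v1, v0, tolerance = 1e-7)
})

test_that("PERMDISP measures within-group spread around the spatial median", {
  # a group on a circle of radius r has every distance equal to r
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  circle <- cbind(2 * cos(th), 2 * sin(th))
  blob <- matrix(rnorm(24, 10, 0.3), 12, 2)
  pd <- permdisp(rbind(circle, blob), rep(c("ring", "blob"), each = 12),
                 n_perms = 49, seed = 4)
  expect_equal(unname(pd$group_means["ring"]), 2, tolerance = 1e-6)
  # singleton groups sit at distance zero from their own median
  one <- rbind(circle, c(5, 5))
  pd1 <- permdisp(one, c(rep("ring", 12), "solo"), n_perms = 19, seed = 5)
  expect_equal(unname(pd1$group_means["solo"]), 0)
  # translating one whole group leaves the dispersions unchanged
  shifted <- rbind(circle, sweep(blob, 2, c(100, -50), "+"))
  pd2 <- permdisp(rbind(circle, blob), rep(c("r", "b"), each = 12),
                  n_perms = 1, seed = 6)
  pd3 <- permdisp(shifted, rep(c("r", "b"), each = 12),
                  n_perms = 1, seed = 6)
  expect_lt(abs(pd2$F - pd3$F), 1e-8)
  # two translated copies of one cloud have F ~ 0 and a large p
  same_cloud <- rbind(blob, sweep(blob, 2, c(3, 3), "+"))
  pd5 <- permdisp(same_cloud, rep(c("x", "y"), each = 12),
                  n_perms = 99, seed = 8)
  expect_lt(pd5$F, 1e-10)
  expect_gt(pd5$p_value, 0.9)
})

test_that("PERMDISP's observed F matches vegan's spatial-median betadisper", {
  set.seed(74)
  sc <- matrix(rnorm(40 * 3), 40, 3)
  grp <- rep(c("A", "B"), each = 20)
  pd <- permdisp(sc, grp, n_perms = 1, seed = 1)
  bd <- vegan::betadisper(dist(sc), grp, type = "median")
  f_vegan <- anova(bd)[["F value"]][1]
  expect_equal(pd$F, f_vegan, tolerance = 1e-4)
  # and the centroid variant against type = "centroid"
  pdc <- permdisp(sc, grp, n_perms = 1, seed = 1, center = "centroid")
  bdc <- vegan::betadisper(dist(sc), grp, type = "centroid")
  expect_equal(pdc$F, anova(bdc)[["F value"]][1], tolerance = 1e-8)
})

test_that("the relatedness suite reruns both tests under three labelings", {
  cfg <- synthetic_config(seed = 81)
  tab <- simulate_fuzzy_table(cfg)
  m <- ipca(standardize_by_group(tab))
  sc <- m$scores[, 1:4]
  suite <- run_relatedness_suite(sc, tab$taxa$group, tab$taxa$group_full,
                                 n_perms = 49, seed = 9)
  expect_equal(suite$pooled$permanova$df_between, 11L)
  expect_equal(suite$full$permanova$df_between,
               length(unique(tab$taxa$group_full)) - 1L)
  kept <- tab$taxa$group != "Others"
  expect_equal(suite$omitted$permanova$df_between,
               length(unique(tab$taxa$group_full[kept])) - 1L)
  expect_equal(suite$n_omitted, 32L)
  # planted syndromes: every labeling rejects
  expect_lte(suite$pooled$permanova$p_value, 0.05)
  expect_lte(suite$full$permanova$p_value, 0.05)
  expect_lte(suite$omitted$permanova$p_value, 0.05)
})
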