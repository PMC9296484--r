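test_that("default configuration reproduces the study-scale data shape", {
  cfg <- synthetic_config()
  expect_equal(sum(cfg$n_taxa_per_group), 596L)
  expect_length(cfg$n_taxa_per_group, 12L)
  tab <- simulate_fuzzy_table(cfg)
  expect_equal(dim(tab$matrix), c(596L, 63L))
  expect_true(all(trait_mask(tab)))
  expect_equal(sum(tab$taxa$group == "Others"), 32L)
  expect_equal(length(unique(tab$taxa$group_full)), 21L)  # 11 named + 10 small
})

test_that("archetypes respond to syndrome strength and are reproducible", {
  cfg0 <- synthetic_config(syndrome_strength = 0, seed = 5)
  a0 <- generate_archetypes(cfg0)
  expect_equal(dim(a0), c(12L, 63L))
  expect_true(all(apply(a0, 2, function(col) diff(range(col)) == 0)))

  cfg1 <- synthetic_config(syndrome_strength = 1, seed = 5)
  a1 <- generate_archetypes(cfg1)
  expect_identical(a1, generate_archetypes(cfg1))
  dmin <- min(dist(a1))
  expect_gt(dmin, 0)
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("simulated codes follow archetype + noise -> clip -> scale -> round", {
  # no noise, no syndrome: every taxon is the shared archetype, all rows equal
  cfg <- synthetic_config(noise_sd = 0, syndrome_strength = 0, seed = 3)
  tab <- simulate_fuzzy_table(cfg)
  expect_true(all(apply(tab$matrix, 2, function(col) length(unique(col)) == 1)))
  # codes are the rounded scaled archetype
  arch <- generate_archetypes(cfg)
  maxes <- cfg$dictionary$traits$max_code
  expected <- as.integer(sign(arch[1, ] * maxes) * floor(abs(arch[1, ] * maxes) + 0.5))
  expect_equal(unname(tab$matrix[1, ]), expected)
  # archetype pinned at 1 gives the maximum code everywhere
  two_group <- synthetic_config(
    n_taxa_per_group = c(X = 2L, Y = 2L), syndrome_strength = 0,
    noise_sd = 0, others_label = "none", seed = 1)
  arch_one <- generate_archetypes(two_group)
  tab_max <- simulate_fuzzy_table(two_group)
  full <- which(arch_one[1, ] > 0.9999)
  if (length(full))
    expect_true(all(tab_max$matrix[, full] ==
                      matrix(maxes[full], 4, length(full), byrow = TRUE)))
  expect_true(all(tab_max$matrix <= matrix(maxes, 4, 63, byrow = TRUE)))
})

test_that("missingness injection is Bernoulli per cell and seed-stable", {
  cfg <- synthetic_config(seed = 11)
  tab <- simulate_fuzzy_table(cfg)
  expect_identical(inject_missingness(tab, 0, 1), tab)
  m1 <- inject_missingness(tab, 0.0103, 99)
  m2 <- inject_missingness(tab, 0.0103, 99)
  expect_identical(trait_mask(m1), trait_mask(m2))
  expect_error(inject_missingness(tab, 1, 1), "rate")

  # mean missing count over 200 seeds within 3 SE of the binomial mean
  n_cells <- length(tab$matrix)
  counts <- vapply(1:200, function(s)
    summarize_missing(inject_missingness(tab, 0.0103, s))$count, numeric(1))
  mu <- n_cells * 0.0103
  se <- sqrt(n_cells * 0.0103 * (1 - 0.0103) / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("planted syndromes are recovered downstream; no syndrome, no signal", {
  # recovery: default strength/noise must separate the groups essentially always
  hits <- vapply(1:25, function(r) {
    cfg <- synthetic_config(seed = 1000 + r)
    tab <- simulate_fuzzy_table(cfg, missing = TRUE)
    m <- ipca(standardize_by_group(tab))
    k <- max(m$retained, 2L)
    pm <- permanova(m$scores[, seq_len(k), drop = FALSE], tab$taxa$group,
                    n_perms = 99, seed = r)
    pm$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # calibration: with no syndrome the labels are exchangeable, so the
  # PERMANOVA p-value is uniform and rejects at about the nominal rate
  small <- c(A = 20L, B = 20L, C = 20L)
  rej <- vapply(1:200, function(r) {
    cfg <- synthetic_config(n_taxa_per_group = small, syndrome_strength = 0,
                            others_label = "none", seed = 2000 + r)
    tab <- simulate_fuzzy_table(cfg)
    m <- ipca(standardize_by_group(tab))
    pm <- permanova(m$scores[, 1:4], tab$taxa$group, n_perms = 99, seed = r)
    pm$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
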