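test_that("loading a delimited table builds matrix and mask correctly", {
  d <- tiny_dictionary()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tgroup\tG1\tG2\tG3\tS1\tS2",
               "tx1\tA\t3\t0\t1\t0\t5",
               "tx2\tB\t2\tNA\t0\t\t4"), f)
  tab <- load_fuzzy_table(f, d)
  expect_equal(dim(tab$matrix), c(2L, 5L))
  expect_true(all(trait_mask(tab)[1, ]))
  expect_equal(unname(trait_mask(tab)[2, ]), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(unname(tab$matrix[1, ]), c(3L, 0L, 1L, 0L, 5L))
  expect_equal(tab$taxa$group, c("A", "B"))
})

test_that("out-of-range and unknown-column inputs are rejected", {
  d <- tiny_dictionary()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tgroup\tG1\tG2\tG3\tS1\tS2",
               "tx1\tA\t7\t0\t1\t0\t5"), f)
  expect_error(load_fuzzy_table(f, d), "exceeds the group's maximum code 3")
  writeLines(c("taxon\tgroup\tG1\tG2\tG3\tS1\tBOGUS",
               "tx1\tA\t1\t0\t1\t0\t5"), f)
  expect_error(load_fuzzy_table(f, d), "not in the dictionary: BOGUS")
  expect_error(fuzzy_trait_table(matrix(-1L, 1, 5),
                                 data.frame(taxon = "t", group = "A"),
                                 d),
               "non-negative")
})

test_that("write then load reproduces matrix and mask bit-exactly", {
  tab <- tiny_table()
  tab$matrix[2, 4] <- NA
  tab <- fuzzy_trait_table(tab$matrix, tab$taxa, tab$dictionary)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fuzzy_table(tab, f)
  tab2 <- load_fuzzy_table(f, tiny_dictionary())
  expect_identical(unname(tab2$matrix), unname(tab$matrix))
  expect_identical(trait_mask(tab2), trait_mask(tab))
})

test_that("merging appends rows over the base trait set with zero fill", {
  base <- tiny_table()
  # an 'addition' region scored without the G3 and S2 traits, and with its
  # own name for G1
  add_dict <- trait_dictionary(list(
    list(name = "Feeding", max_code = 3,
         traits = data.frame(name = c("Herbivore", "Predator"),
                             abbr = c("H1", "G2"))),
    list(name = "Size", max_code = 5,
         traits = data.frame(name = "Small", abbr = "S1"))))
  add <- fuzzy_trait_table(matrix(c(1L, 2L, 3L), 1, 3),
                           data.frame(taxon = "new1", group = "C"),
                           add_dict)
  merged <- merge_tables(base, add, name_map = c(H1 = "G1"),
                         zero_fill = c("G3", "S2"))
  expect_equal(nrow(merged$matrix), 5L)
  expect_equal(colnames(merged$matrix), colnames(base$matrix))
  expect_equal(unname(merged$matrix[5, ]), c(1L, 2L, 0L, 3L, 0L))
  # zero-filled cells are observed zeros, not missing
  expect_true(all(trait_mask(merged)[5, c("G3", "S2")]))

  expect_error(merge_tables(base, add, zero_fill = c("G3", "S2")),
               "supply name_map")
  dup <- fuzzy_trait_table(matrix(0L, 1, 3),
                           data.frame(taxon = "tx1", group = "C"), add_dict)
  expect_error(merge_tables(base, dup, name_map = c(H1 = "G1"),
                            zero_fill = c("G3", "S2")),
               "taxon id present in both")
  empty <- fuzzy_trait_table(matrix(integer(0), 0, 3),
                             data.frame(taxon = character(0),
                                        group = character(0)), add_dict)
  expect_identical(merge_tables(base, empty), base)
})

test_that("group-wise standardization maps codes onto [0,1] by max code", {
  tab <- tiny_table()
  tab$matrix[2, 4] <- NA
  tab <- fuzzy_trait_table(tab$matrix, tab$taxa, tab$dictionary)
  std <- standardize_by_group(tab)
  expect_equal(std$matrix[1, "G1"], 1)        # 3 on a 0-3 scale
  expect_equal(std$matrix[1, "S2"], 1)        # 5 on a 0-5 scale
  expect_equal(std$matrix[3, "S1"], 1)        # 5/5
  expect_equal(std$matrix[2, "S2"], 4 / 5)    # 4 on a 0-5 scale
  expect_true(all(std$matrix >= 0 & std$matrix <= 1, na.rm = TRUE))
  expect_identical(trait_mask(std), trait_mask(tab))
  # observed_minmax divides by the observed per-group maximum instead
  alt <- standardize_by_group(tab, "observed_minmax")
  expect_equal(alt$matrix[2, "G1"], 2 / 3)
  expect_true(all(vapply(unique(tab$dictionary$traits$group), function(g) {
    cols <- tab$dictionary$traits$group == g
    max(alt$matrix[, cols], na.rm = TRUE) == 1
  }, logical(1))))
})

test_that("missing-cell summaries count and percentage match", {
  tab <- tiny_table()
  expect_equal(summarize_missing(tab), list(count = 0L, percent = 0))
  m <- tab$matrix
  m[1, 1] <- NA
  tab1 <- fuzzy_trait_table(m, tab$taxa, tab$dictionary)
  expect_equal(summarize_missing(tab1)$count, 1L)
  expect_equal(summarize_missing(tab1)$percent, 5)  # 1 of 20 cells
})
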