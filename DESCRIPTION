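Package: traitspacer
Title: Functional Trait Space Analysis for Fuzzy-Coded Trait Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the functional trait space of species
    assemblages described by fuzzy-coded biological traits, developed around
    freshwater macroinvertebrate trait databases. Provides group-wise [0,1]
    standardization of fuzzy affinity scores, centred principal component
    analysis that tolerates missing cells (pairwise-deletion covariance),
    broken-stick axis selection and trait-axis correlation screening,
    d-dimensional convex-hull volumes with centroid-fraction outlier trimming,
    Monte-Carlo null models of trait-space occupancy (uniform, normal, and
    per-axis permutation), and permutation tests of taxonomic constraint
    (PERMANOVA and spatial-median PERMDISP). A synthetic-data generator with
    planted taxonomic-group trait syndromes makes the whole pipeline runnable
    and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
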