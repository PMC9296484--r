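#' Configuration for synthetic fuzzy trait tables
#'
#' Builds the parameter set for the synthetic-data generator. The generator
#' emulates the statistical structure of a continental fuzzy-coded
#' macroinvertebrate trait database: integer affinity codes on per-group 0-3
#' or 0-5 scales, taxonomic groups whose members share a trait syndrome (so
#' groups separate in ordination space), and a small fraction of missing
#' cells. Defaults mirror that setting: 596 taxa in 12 taxonomic groups (11
#' named groups plus an "Others" pool of small groups), the bundled 11-group
#' / 63-trait dictionary, and a 1.03% missing-cell rate.
#'
#' @param n_taxa_per_group named integer vector of taxa counts per
#'   taxonomic group. The default allocates 596 taxa over 12 groups.
#' @param dictionary a [trait_dictionary()]; default the bundled one.
#' @param syndrome_strength in \[0,1\]: 0 makes all group archetypes
#'   identical (no group structure), 1 makes them independent draws.
#' @param noise_sd standard deviation of the Gaussian taxon-level noise
#'   added to the group archetype on the \[0,1\] affinity scale.
#' @param missing_rate probability that a cell is masked as missing by
#'   [inject_missingness()] (only applied when `simulate_fuzzy_table()` is
#'   called with `missing = TRUE`).
#' @param others_label name of the pooled small-group category; taxa in it
#'   are also assigned a fine-grained label from `others_groups` so analyses
#'   can be rerun with the pool broken into its member groups.
#' @param others_groups named integer vector of fine-grained group sizes
#'   within the pool; must sum to `n_taxa_per_group[others_label]`.
#' @param seed integer seed; identical config and seed give identical tables.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa_per_group = NULL,
                             dictionary = default_trait_dictionary(),
                             syndrome_strength = 0.7,
                             noise_sd = 0.15,
                             missing_rate = 0.0103,
                             others_label = "Others",
                             others_groups = NULL,
                             seed = 1L) {
  if (is.null(n_taxa_per_group))
    n_taxa_per_group <- c(
      Annelida = 42L, Gastropoda = 41L, Bivalvia = 10L, Crustacea = 28L,
      Ephemeroptera = 37L, Plecoptera = 31L, Odonata = 39L, Heteroptera = 29L,
      Coleoptera = 173L, Trichoptera = 96L, Diptera = 38L, Others = 32L)
  if (is.null(names(n_taxa_per_group)) || any(!nzchar(names(n_taxa_per_group))))
    stop("'n_taxa_per_group' must be a named vector")
  if (any(n_taxa_per_group < 1))
    stop("every taxonomic group needs at least one taxon")
  if (syndrome_strength < 0 || syndrome_strength > 1)
    stop("'syndrome_strength' must be in [0,1]")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0,1)")
  stopifnot(inherits(dictionary, "trait_dictionary"))
  if (others_label %in% names(n_taxa_per_group) && is.null(others_groups)) {
    pool <- n_taxa_per_group[[others_label]]
    small <- c("Porifera", "Cnidaria", "Bryozoa", "Platyhelminthes", "Nemertea",
               "Nematomorpha", "Hymenoptera", "Lepidoptera", "Megaloptera",
               "Neuroptera")
    sizes <- rep(pool %/% length(small), length(small))
    extra <- pool - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    keep <- sizes > 0
    others_groups <- stats::setNames(as.integer(sizes[keep]), small[keep])
  }
  if (!is.null(others_groups) && others_label %in% names(n_taxa_per_group) &&
      sum(others_groups) != n_taxa_per_group[[others_label]])
    stop("'others_groups' sizes must sum to the '", others_label, "' group size")
  structure(list(n_taxa_per_group = n_taxa_per_group, dictionary = dictionary,
                 syndrome_strength = syndrome_strength, noise_sd = noise_sd,
                 missing_rate = missing_rate, others_label = others_label,
                 others_groups = others_groups, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Group trait-syndrome archetypes
#'
#' Draws one continuous trait profile (values in \[0,1\] per trait) per
#' taxonomic group. Each profile is a mixture of a shared baseline profile
#' and a group-specific profile, weighted by `syndrome_strength`; both are
#' drawn from a U-shaped Beta(0.4, 0.4) so affinities pile up near 0 and 1,
#' as fuzzy-coded profiles do in practice. Deterministic given the config
#' seed.
#'
#' @param config a [synthetic_config()].
#' @return A groups-by-traits numeric matrix with group names as row names.
#' @export
generate_archetypes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- nrow(config$dictionary$traits)
  groups <- names(config$n_taxa_per_group)
  s <- config$syndrome_strength
  with_seed(substream_seed(config$seed, "archetypes"), {
    baseline <- stats::rbeta(p, 0.4, 0.4)
    prof <- t(vapply(groups, function(g) {
      (1 - s) * baseline + s * stats::rbeta(p, 0.4, 0.4)
    }, numeric(p)))
  })
  dimnames(prof) <- list(groups, config$dictionary$traits$abbr)
  prof
}

#' Simulate a fuzzy-coded trait table
#'
#' For each taxon, the continuous affinity on every trait is its group
#' archetype plus Gaussian noise (`noise_sd`), clipped to \[0,1\], scaled by
#' the trait group's maximum code and rounded to the nearest integer (half
#' away from zero, so fixtures are platform-stable). The result is a fully
#' observed [fuzzy_trait_table()]; set `missing = TRUE` to additionally mask
#' cells at the configured `missing_rate`.
#'
#' @param config a [synthetic_config()].
#' @param missing apply [inject_missingness()] at `config$missing_rate`?
#' @return A [fuzzy_trait_table()] with `sum(n_taxa_per_group)` taxa.
#' @export
simulate_fuzzy_table <- function(config, missing = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  arch <- generate_archetypes(config)
  counts <- config$n_taxa_per_group
  n <- sum(counts)
  p <- ncol(arch)
  maxes <- config$dictionary$traits$max_code
  group <- rep(names(counts), counts)
  cont <- with_seed(substream_seed(config$seed, "noise"), {
    arch[group, , drop = FALSE] +
      matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  })
  cont <- pmin(pmax(cont, 0), 1)
  codes <- round_half_away(sweep(cont, 2L, maxes, "*"))
  taxa <- data.frame(taxon = sprintf("t%04d", seq_len(n)), group = group,
                     group_full = group, stringsAsFactors = FALSE)
  if (!is.null(config$others_groups) && config$others_label %in% names(counts)) {
    fine <- rep(names(config$others_groups), config$others_groups)
    taxa$group_full[taxa$group == config$others_label] <- fine
  }
  tab <- fuzzy_trait_table(codes, taxa, config$dictionary)
  if (missing && config$missing_rate > 0)
    tab <- inject_missingness(tab, config$missing_rate,
                              substream_seed(config$seed, "missingness"))
  tab
}

#' Mask cells of a trait table at random
#'
#' Marks each cell missing independently with probability `rate`, emulating
#' the unknown entries of expert-scored trait databases (missing completely
#' at random). Deterministic given the seed.
#'
#' @param table a [fuzzy_trait_table()].
#' @param rate missingness probability in \[0,1).
#' @param seed integer seed.
#' @return A [fuzzy_trait_table()] with the same values where observed.
#' @export
inject_missingness <- function(table, rate, seed) {
  stopifnot(inherits(table, "fuzzy_trait_table"))
  if (rate < 0 || rate >= 1) stop("'rate' must be in [0,1)")
  if (rate == 0) return(table)
  m <- table$matrix
  drop <- with_seed(seed, stats::runif(length(m)) < rate)
  m[drop] <- NA_integer_
  fuzzy_trait_table(m, table$taxa, table$dictionary)
}
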