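#' Trait dictionaries
#'
#' A trait dictionary describes the structure of a fuzzy-coded trait table:
#' an ordered list of trait groups, each holding an ordered list of trait
#' states (with a short unique abbreviation) and the maximum affinity code of
#' the group. Fuzzy coding scores the affinity of a taxon to each state of a
#' trait group on an integer scale from 0 (no affinity) up to the group's
#' `max_code` (3 for groups with few states, 5 for groups with many states in
#' the bundled dictionary), so a taxon can belong partially to several states
#' at once.
#'
#' `trait_dictionary()` builds and validates a dictionary from a list of group
#' records; `load_trait_dictionary()` reads one from JSON or TSV;
#' `default_trait_dictionary()` returns the dictionary bundled with the
#' package: 11 trait groups with a total of 63 trait states describing feeding
#' habit, locomotion, food type, respiration, maximal size, resistance form,
#' dispersal, aquatic stage, life cycle duration, voltinism and reproduction
#' of freshwater macroinvertebrates, abbreviated FH1 ... RP8.
#'
#' @param groups a list of group records, each a list with elements `name`
#'   (character), `max_code` (positive integer) and `traits` (a data frame or
#'   list of records with elements `name` and `abbr`).
#' @return An object of class `trait_dictionary`: a list with elements
#'   `groups` (a data frame with columns `group`, `max_code`, `n_traits`) and
#'   `traits` (a data frame with columns `group`, `name`, `abbr`,
#'   `max_code`), ordered as supplied.
#' @examples
#' d <- default_trait_dictionary()
#' d
#' n_traits(d)
#' @export
trait_dictionary <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("'groups' must be a non-empty list of group records")
  grp_rows <- list()
  trait_rows <- list()
  for (g in groups) {
    if (is.null(g$name) || !nzchar(g$name))
      stop("every trait group needs a non-empty 'name'")
    mc <- g$max_code
    if (is.null(mc) || length(mc) != 1L || is.na(mc) || mc < 1 || mc != round(mc))
      stop("trait group '", g$name, "': 'max_code' must be a positive integer")
    tr <- g$traits
    if (is.data.frame(tr)) {
      tnames <- as.character(tr$name)
      tabbr <- as.character(tr$abbr)
    } else {
      tnames <- vapply(tr, function(t) as.character(t$name), character(1))
      tabbr <- vapply(tr, function(t) as.character(t$abbr), character(1))
    }
    if (length(tnames) == 0L)
      stop("trait group '", g$name, "' has no traits")
    if (anyNA(tnames) || anyNA(tabbr) || any(!nzchar(tabbr)))
      stop("trait group '", g$name, "': every trait needs a name and abbreviation")
    grp_rows[[length(grp_rows) + 1L]] <- data.frame(
      group = g$name, max_code = as.integer(mc), n_traits = length(tnames),
      stringsAsFactors = FALSE)
    trait_rows[[length(trait_rows) + 1L]] <- data.frame(
      group = g$name, name = tnames, abbr = tabbr,
      max_code = as.integer(mc), stringsAsFactors = FALSE)
  }
  grp <- do.call(rbind, grp_rows)
  traits <- do.call(rbind, trait_rows)
  rownames(grp) <- rownames(traits) <- NULL
  if (anyDuplicated(grp$group))
    stop("duplicate trait group name: ",
         paste(unique(grp$group[duplicated(grp$group)]), collapse = ", "))
  if (anyDuplicated(traits$abbr))
    stop("duplicate trait abbreviation: ",
         paste(unique(traits$abbr[duplicated(traits$abbr)]), collapse = ", "))
  structure(list(groups = grp, traits = traits), class = "trait_dictionary")
}

#' @rdname trait_dictionary
#' @param path path to a dictionary file. JSON files must hold
#'   `{"groups": [{"name", "max_code", "traits": [{"name", "abbr"}]}]}`; TSV
#'   files must have columns `group`, `max_code`, `name` (or `trait`), `abbr`,
#'   one row per trait state, groups in order of first appearance.
#' @export
load_trait_dictionary <- function(path) {
  if (!file.exists(path)) stop("trait dictionary file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(raw$groups)) stop("dictionary JSON must have a top-level 'groups' array")
    return(trait_dictionary(raw$groups))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  name_col <- if ("name" %in% names(tab)) "name" else "trait"
  need <- c("group", "max_code", name_col, "abbr")
  if (!all(need %in% names(tab)))
    stop("dictionary TSV must have columns: group, max_code, name (or trait), abbr")
  groups <- lapply(unique(tab$group), function(gn) {
    rows <- tab[tab$group == gn, , drop = FALSE]
    list(name = gn, max_code = rows$max_code[1L],
         traits = data.frame(name = rows[[name_col]], abbr = rows$abbr,
                             stringsAsFactors = FALSE))
  })
  trait_dictionary(groups)
}

#' @rdname trait_dictionary
#' @export
default_trait_dictionary <- function() {
  path <- system.file("extdata", "trait_dictionary.json", package = "traitspacer",
                      mustWork = TRUE)
  load_trait_dictionary(path)
}

#' @rdname trait_dictionary
#' @param x a `trait_dictionary`.
#' @export
n_traits <- function(x) {
  stopifnot(inherits(x, "trait_dictionary"))
  nrow(x$traits)
}

#' @rdname trait_dictionary
#' @export
n_trait_groups <- function(x) {
  stopifnot(inherits(x, "trait_dictionary"))
  nrow(x$groups)
}

#' @export
print.trait_dictionary <- function(x, ...) {
  cat("Trait dictionary:", nrow(x$groups), "trait groups,",
      nrow(x$traits), "traits\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %-36s %2d traits, codes 0-%d\n", x$groups$group[i],
                x$groups$n_traits[i], x$groups$max_code[i]))
  invisible(x)
}

# write a dictionary back to TSV (round-trip support for user edits)
#' @rdname trait_dictionary
#' @param file output path for `write_trait_dictionary()`.
#' @export
write_trait_dictionary <- function(x, file) {
  stopifnot(inherits(x, "trait_dictionary"))
  utils::write.table(x$traits[, c("group", "max_code", "name", "abbr")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
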