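#' Fuzzy-coded trait tables
#'
#' A fuzzy trait table is a taxa-by-traits matrix of integer affinity codes
#' together with per-taxon taxonomic-group labels and a trait dictionary
#' describing the columns. Missing cells (trait affinities unknown for a
#' taxon) are held as `NA` and are distinguished from observed zeros
#' (affinity known to be absent). Column order always follows the
#' dictionary's trait order.
#'
#' @param matrix an integer taxa-by-traits matrix; `NA` marks missing cells.
#' @param taxa a data frame with columns `taxon` (unique ids) and `group`
#'   (taxonomic-group label); an optional `group_full` column may carry a
#'   finer-grained label set (e.g. the real taxonomic groups pooled into an
#'   "Others" reporting group).
#' @param dictionary a [trait_dictionary()].
#' @return An object of class `fuzzy_trait_table`: a list with elements
#'   `matrix`, `taxa`, `dictionary`.
#' @export
fuzzy_trait_table <- function(matrix, taxa, dictionary) {
  stopifnot(inherits(dictionary, "trait_dictionary"))
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != nrow(dictionary$traits))
    stop("matrix has ", ncol(matrix), " columns but the dictionary defines ",
         nrow(dictionary$traits), " traits")
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- dictionary$traits$abbr
  } else if (!identical(colnames(matrix), dictionary$traits$abbr)) {
    if (!setequal(colnames(matrix), dictionary$traits$abbr))
      stop("matrix column names do not match the dictionary's trait abbreviations")
    matrix <- matrix[, dictionary$traits$abbr, drop = FALSE]
  }
  if (!is.data.frame(taxa) || !all(c("taxon", "group") %in% names(taxa)))
    stop("'taxa' must be a data frame with columns 'taxon' and 'group'")
  taxa$taxon <- as.character(taxa$taxon)
  taxa$group <- as.character(taxa$group)
  if (nrow(taxa) != nrow(matrix))
    stop("taxa metadata has ", nrow(taxa), " rows but matrix has ", nrow(matrix))
  if (anyDuplicated(taxa$taxon))
    stop("duplicate taxon id: ",
         paste(unique(taxa$taxon[duplicated(taxa$taxon)]), collapse = ", "))
  obs <- !is.na(matrix)
  vals <- matrix[obs]
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("trait affinities must be non-negative integers")
  maxes <- dictionary$traits$max_code
  for (j in seq_len(ncol(matrix))) {
    bad <- which(obs[, j] & matrix[, j] > maxes[j])
    if (length(bad))
      stop("value ", matrix[bad[1L], j], " in trait '", colnames(matrix)[j],
           "' (row ", bad[1L], ") exceeds the group's maximum code ", maxes[j])
  }
  storage.mode(matrix) <- "integer"
  rownames(matrix) <- taxa$taxon
  structure(list(matrix = matrix, taxa = taxa, dictionary = dictionary),
            class = "fuzzy_trait_table")
}

#' @rdname fuzzy_trait_table
#' @param x a `fuzzy_trait_table` or `standardized_trait_table`.
#' @return `trait_mask()` returns the logical taxa-by-traits presence mask
#'   (`TRUE` = value observed).
#' @export
trait_mask <- function(x) {
  stopifnot(inherits(x, c("fuzzy_trait_table", "standardized_trait_table")))
  !is.na(x$matrix)
}

#' @export
print.fuzzy_trait_table <- function(x, ...) {
  m <- summarize_missing(x)
  cat("Fuzzy trait table:", nrow(x$matrix), "taxa x", ncol(x$matrix), "traits\n")
  cat("Taxonomic groups:", length(unique(x$taxa$group)), "\n")
  cat(sprintf("Missing cells: %d (%.2f%%)\n", m$count, m$percent))
  invisible(x)
}

#' Read a fuzzy trait table from delimited text
#'
#' Reads a TSV/CSV file with one row per taxon, metadata columns for the
#' taxon id and taxonomic group, and one integer column per trait. Trait
#' columns are matched to the dictionary by abbreviation or by full trait
#' name; empty cells and missing-value sentinels become missing cells.
#'
#' @param path input file; the delimiter is taken from the extension
#'   (`.csv` = comma, anything else = tab) unless `sep` is given.
#' @param dictionary a [trait_dictionary()].
#' @param taxon_col,group_col names of the metadata columns (defaults
#'   `"taxon"`, `"group"`).
#' @param group_full_col optional column with fine-grained group labels.
#' @param na_strings cell values treated as missing, matched
#'   case-insensitively after trimming; the empty string is always missing.
#' @param sep field separator override.
#' @return A [fuzzy_trait_table()].
#' @export
load_fuzzy_table <- function(path, dictionary, taxon_col = "taxon",
                             group_col = "group", group_full_col = NULL,
                             na_strings = c("NA", "NaN"), sep = NULL) {
  if (!file.exists(path)) stop("trait table file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  for (col in c(taxon_col, group_col, group_full_col))
    if (!col %in% names(raw))
      stop("metadata column '", col, "' not found in ", path)
  meta_cols <- c(taxon_col, group_col, group_full_col)
  trait_cols <- setdiff(names(raw), meta_cols)
  # accept either abbreviations or full trait names as headers
  idx <- match(trait_cols, dictionary$traits$abbr)
  by_name <- match(trait_cols, dictionary$traits$name)
  idx[is.na(idx)] <- by_name[is.na(idx)]
  if (anyNA(idx))
    stop("trait columns not in the dictionary: ",
         paste(trait_cols[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx))
    stop("trait referenced by more than one column: ",
         paste(dictionary$traits$abbr[idx[duplicated(idx)]], collapse = ", "))
  if (length(trait_cols) != nrow(dictionary$traits))
    stop("table has ", length(trait_cols), " trait columns but the dictionary ",
         "defines ", nrow(dictionary$traits), " traits; missing: ",
         paste(setdiff(dictionary$traits$abbr, dictionary$traits$abbr[idx]),
               collapse = ", "))
  vals <- as.matrix(raw[, trait_cols, drop = FALSE])[, order(idx), drop = FALSE]
  vals <- trimws(vals)
  vals[vals == "" | tolower(vals) %in% tolower(na_strings)] <- NA
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.na(vals) & is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric trait value '", vals[bad[1L, , drop = FALSE]],
         "' at row ", bad[1L, 1L])
  colnames(num) <- dictionary$traits$abbr
  taxa <- data.frame(taxon = raw[[taxon_col]], group = raw[[group_col]],
                     stringsAsFactors = FALSE)
  if (!is.null(group_full_col)) taxa$group_full <- raw[[group_full_col]]
  fuzzy_trait_table(num, taxa, dictionary)
}

#' Write a fuzzy trait table to TSV
#'
#' Writes the table in the layout [load_fuzzy_table()] reads (metadata
#' columns first, then trait columns keyed by abbreviation; missing cells as
#' `NA`), so a write/load round trip reproduces matrix and mask exactly.
#'
#' @param x a [fuzzy_trait_table()].
#' @param file output path.
#' @export
write_fuzzy_table <- function(x, file) {
  stopifnot(inherits(x, "fuzzy_trait_table"))
  out <- cbind(x$taxa, as.data.frame(x$matrix, check.names = FALSE))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(file)
}

#' Merge two fuzzy trait tables over a common trait set
#'
#' Row-concatenates an addition table (e.g. taxa from another biogeographic
#' region scored with a slightly different trait list) onto a base table.
#' Addition traits may first be renamed to their base equivalents via
#' `name_map`; traits the addition was never scored for can be declared in
#' `zero_fill`, in which case the added taxa receive an explicit affinity of
#' 0 for them — an observed zero, not a missing value, the assumption being
#' that those taxa have no affinity for the unscored states.
#'
#' @param base a [fuzzy_trait_table()] holding the full trait set.
#' @param addition a `fuzzy_trait_table` whose traits, after renaming, form a
#'   subset of the base traits.
#' @param name_map named character vector mapping addition trait names or
#'   abbreviations to base abbreviations (`c("Detritus < 1 mm" = "FT2")`).
#' @param zero_fill character vector of base trait abbreviations absent from
#'   the addition, to be filled with observed zeros.
#' @return A `fuzzy_trait_table` over the base dictionary with
#'   `nrow(base) + nrow(addition)` taxa.
#' @export
merge_tables <- function(base, addition, name_map = NULL, zero_fill = character()) {
  stopifnot(inherits(base, "fuzzy_trait_table"),
            inherits(addition, "fuzzy_trait_table"))
  if (nrow(addition$matrix) == 0L) return(base)
  add_abbr <- colnames(addition$matrix)
  if (!is.null(name_map)) {
    hit <- match(add_abbr, names(name_map))
    add_abbr[!is.na(hit)] <- unname(name_map[hit[!is.na(hit)]])
  }
  base_abbr <- colnames(base$matrix)
  unknown <- setdiff(add_abbr, base_abbr)
  if (length(unknown))
    stop("addition traits not present in the base table (supply name_map): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(add_abbr))
    stop("name_map maps two addition traits onto the same base trait: ",
         paste(add_abbr[duplicated(add_abbr)], collapse = ", "))
  bad_fill <- intersect(zero_fill, add_abbr)
  if (length(bad_fill))
    stop("zero_fill traits already present in the addition: ",
         paste(bad_fill, collapse = ", "))
  uncovered <- setdiff(base_abbr, c(add_abbr, zero_fill))
  if (length(uncovered))
    stop("base traits neither scored in the addition nor zero-filled: ",
         paste(uncovered, collapse = ", "))
  dup <- intersect(base$taxa$taxon, addition$taxa$taxon)
  if (length(dup))
    stop("taxon id present in both tables: ", paste(dup, collapse = ", "))
  add_full <- matrix(NA_integer_, nrow(addition$matrix), length(base_abbr),
                     dimnames = list(addition$taxa$taxon, base_abbr))
  add_full[, add_abbr] <- addition$matrix
  if (length(zero_fill)) add_full[, zero_fill] <- 0L
  taxa <- rbind(pad_group_full(base$taxa), pad_group_full(addition$taxa))
  fuzzy_trait_table(rbind(base$matrix, add_full), taxa, base$dictionary)
}

pad_group_full <- function(taxa) {
  if (!"group_full" %in% names(taxa)) taxa$group_full <- taxa$group
  taxa[, c("taxon", "group", "group_full")]
}

#' Standardize fuzzy trait scores to the unit interval, trait group by trait group
#'
#' Fuzzy affinity codes come on different ranges (0-3 or 0-5 depending on the
#' trait group), which would give the wider-coded groups unintended extra
#' weight in any analysis run on the raw codes. Standardizing each trait
#' group separately onto \[0,1\] removes the range difference while keeping
#' the scores of related traits within a group comparable to one another —
#' unlike per-trait standardization, which would destroy the within-group
#' structure.
#'
#' @param table a [fuzzy_trait_table()].
#' @param mode `"max_code"` (default) divides every score in a group by the
#'   group's maximum possible code, so a code of 3 on a 0-3 scale and 5 on a
#'   0-5 scale both map to 1; `"observed_minmax"` rescales each group
#'   linearly so its observed minimum and maximum become 0 and 1 (falling
#'   back to division by the observed maximum when the group minimum is
#'   positive would be arbitrary — the affinity origin 0 is kept fixed, i.e.
#'   scores are divided by the group's observed maximum).
#' @return An object of class `standardized_trait_table`: same shape, taxa
#'   and mask as `table`, real-valued cells in \[0,1\], with the mode in
#'   `$standardization`.
#' @export
standardize_by_group <- function(table, mode = c("max_code", "observed_minmax")) {
  stopifnot(inherits(table, "fuzzy_trait_table"))
  mode <- match.arg(mode)
  m <- table$matrix * 1.0
  maxes <- table$dictionary$traits$max_code
  if (mode == "max_code") {
    if (any(maxes == 0)) stop("dictionary has a trait group with max_code 0")
    m <- sweep(m, 2L, maxes, "/")
  } else {
    for (gn in table$dictionary$groups$group) {
      cols <- which(table$dictionary$traits$group == gn)
      obs_max <- suppressWarnings(max(m[, cols], na.rm = TRUE))
      if (!is.finite(obs_max) || obs_max == 0) obs_max <- 1  # all-zero/empty group
      m[, cols] <- m[, cols] / obs_max
    }
  }
  structure(list(matrix = m, taxa = table$taxa, dictionary = table$dictionary,
                 standardization = mode),
            class = "standardized_trait_table")
}

#' @export
print.standardized_trait_table <- function(x, ...) {
  cat("Standardized trait table:", nrow(x$matrix), "taxa x", ncol(x$matrix),
      "traits (mode:", x$standardization, ")\n")
  invisible(x)
}

#' Count missing cells
#'
#' @param table a [fuzzy_trait_table()] or `standardized_trait_table`.
#' @return A list with `count` (number of missing cells) and `percent`
#'   (share of all cells, in percent, rounded to 2 decimals).
#' @export
summarize_missing <- function(table) {
  stopifnot(inherits(table, c("fuzzy_trait_table", "standardized_trait_table")))
  count <- sum(is.na(table$matrix))
  list(count = count,
       percent = round(100 * count / length(table$matrix), 2))
}
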