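#' Construct a trait table
#'
#' The central data container: a species-by-trait table with an explicit
#' per-column type (continuous or categorical) and a set of columns flagged
#' as always-complete. Missing cells are `NA`. Continuous traits are stored
#' on the scale the analysis uses (natural log for sizes, masses and other
#' positive quantities).
#'
#' @param data A data.frame of trait columns; row names are species labels.
#' @param types Named character vector mapping every column to
#'   `"continuous"` or `"categorical"`.
#' @param complete_cols Character vector of columns that must never contain
#'   missing values (e.g. the response and the tree-matching keys).
#' @return An object of class `"trait_table"` with fields `species`,
#'   `data`, `types` and `complete_cols`.
#' @export
trait_table <- function(data, types, complete_cols = character()) {
  stopifnot(is.data.frame(data), !is.null(rownames(data)))
  if (!setequal(names(types), names(data)))
    stop("`types` must name every column of `data`")
  if (!all(types %in% c("continuous", "categorical")))
    stop("types must be 'continuous' or 'categorical'")
  if (!all(complete_cols %in% names(data)))
    stop("unknown complete_cols: ",
         paste(setdiff(complete_cols, names(data)), collapse = ", "))
  bad <- complete_cols[vapply(complete_cols,
                              function(cl) anyNA(data[[cl]]), logical(1))]
  if (length(bad))
    stop("columns flagged complete contain NA: ", paste(bad, collapse = ", "))
  structure(list(species = rownames(data),
                 data = data,
                 types = types[names(data)],
                 complete_cols = complete_cols),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  mm <- missing_fractions(x)
  cat(sprintf("trait_table: %d species x %d traits (%d continuous, %d categorical)\n",
              length(x$species), ncol(x$data),
              sum(x$types == "continuous"), sum(x$types == "categorical")))
  cat(sprintf("overall missingness %.1f%%; complete columns: %s\n",
              100 * mean(mm), paste(x$complete_cols, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.trait_table <- function(x, ...) x$data

#' Per-column missing fractions of a trait table
#'
#' @param table A [trait_table()].
#' @return Named numeric vector of per-column fractions of missing cells.
#' @export
missing_fractions <- function(table) {
  vapply(table$data, function(cl) mean(is.na(cl)), numeric(1))
}

#' Write a trait table as CSV
#'
#' First column `species`, one column per trait, empty cells for missing
#' values.
#'
#' @param table A [trait_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(table, path) {
  df <- data.frame(species = table$species, table$data,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trait table from CSV
#'
#' Inverse of [write_trait_csv()]. Column types default to continuous for
#' numeric columns and categorical otherwise; empty cells become `NA`.
#'
#' @param path CSV path; first column must be `species`.
#' @param types Optional named type vector overriding the inference.
#' @param complete_cols Columns asserted complete.
#' @return A [trait_table()].
#' @export
read_trait_csv <- function(path, types = NULL, complete_cols = character()) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "species") stop("first CSV column must be 'species'")
  rownames(df) <- df$species
  df$species <- NULL
  if (is.null(types))
    types <- vapply(df, function(cl)
      if (is.numeric(cl)) "continuous" else "categorical", character(1))
  trait_table(df, types, complete_cols)
}

# Align a trait table to a tree: intersect taxa, warn on drops, return
# list(table, tree) in matching lexicographic order.
align_to_tree <- function(table, tree) {
  common <- intersect(table$species, tree$tip.label)
  if (length(common) < 2) stop("fewer than 2 taxa shared by table and tree")
  dropped <- length(table$species) - length(common) +
    length(tree$tip.label) - length(common)
  if (dropped > 0)
    warning(dropped, " taxa dropped in table/tree intersection")
  tree <- sort_tips(ape::keep.tip(tree, common))
  data <- table$data[tree$tip.label, , drop = FALSE]
  list(table = trait_table(data, table$types, table$complete_cols),
       tree = tree)
}
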