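# Internal helpers shared across modules.

# Column names of the paired allele columns, in order, from a counts-like
# tibble (first column "population", then <locus>.A / <locus>.B pairs).
allele_columns <- function(x) {
  setdiff(names(x), c("population", "individual"))
}

# Split "<locus>.<allele>" column names into locus / allele parts.
# The allele suffix is the text after the last dot; loci may contain dots.
split_allele_names <- function(nms) {
  locus <- sub("\\.[AB]$", "", nms)
  allele <- sub("^.*\\.", "", nms)
  ok <- grepl("\\.[AB]$", nms)
  tibble(column = nms, locus = locus, allele = allele, paired_name = ok)
}

# Ordered locus ids of a counts table.
locus_ids <- function(x) {
  unique(split_allele_names(allele_columns(x))$locus)
}

# Extract the numeric matrix of a table (all columns except ids).
table_matrix <- function(x, id_cols = "population") {
  m <- as.matrix(x[, setdiff(names(x), id_cols), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x[[id_cols[1]]]
  m
}

# Stop unless x is a data frame with a leading "population" column.
check_population_frame <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", arg), class = "clineshift_type_error")
  }
  if (!"population" %in% names(x)) {
    abort(sprintf("`%s` must contain a `population` column.", arg),
          class = "clineshift_type_error")
  }
  if (anyDuplicated(x$population) > 0) {
    dup <- x$population[duplicated(x$population)][1]
    abort(sprintf("`%s` has duplicated population id: %s", arg, dup),
          class = "clineshift_validation_error")
  }
  invisible(x)
}

check_no_missing <- function(x, arg = "x") {
  if (anyNA(x)) {
    bad <- names(x)[vapply(x, anyNA, logical(1))]
    abort(sprintf("`%s` contains missing values in: %s (remove incomplete records before analysis)",
                  arg, paste(bad, collapse = ", ")),
          class = "clineshift_validation_error")
  }
  invisible(x)
}

# round-half-up at 0 decimals (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# delimiter by file extension: .csv -> comma, anything else -> tab
reader_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
}

writer_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::write_csv else readr::write_tsv
}
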