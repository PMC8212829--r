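#' Validate a population-level allele count table
#'
#' An allele count table is a tibble with a leading `population` column and,
#' for each biallelic locus, a pair of nonnegative integer columns named
#' `<locus>.A` and `<locus>.B` holding the counts of the two alleles sampled
#' in each population. The total number of alleles sampled per population,
#' `N`, must be identical across loci (no missing genotypes).
#'
#' @param x A data frame of population allele counts.
#' @return `x` as a tibble, invisibly validated (errors on violation).
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   population = c("P1", "P2"),
#'   L1.A = c(3L, 5L), L1.B = c(7L, 5L)
#' )
#' validate_allele_counts(counts)
validate_allele_counts <- function(x) {
  check_population_frame(x, "x")
  cols <- allele_columns(x)
  info <- split_allele_names(cols)
  if (!all(info$paired_name)) {
    abort(sprintf("allele columns must be named <locus>.A / <locus>.B; offending: %s",
                  paste(info$column[!info$paired_name], collapse = ", ")),
          class = "clineshift_format_error")
  }
  wide <- tidyr::pivot_wider(info, id_cols = "locus",
                             names_from = "allele", values_from = "column")
  if (!all(c("A", "B") %in% names(wide)) || anyNA(wide$A) || anyNA(wide$B)) {
    missing_side <- if (!"B" %in% names(wide)) wide$locus else
      wide$locus[is.na(wide$A) | is.na(wide$B)]
    abort(sprintf("unpaired allele column(s) for locus: %s",
                  paste(missing_side, collapse = ", ")),
          class = "clineshift_format_error")
  }
  check_no_missing(x, "x")
  m <- table_matrix(x)
  if (any(m < 0)) {
    abort("allele counts must be nonnegative", class = "clineshift_validation_error")
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    abort("allele counts must be integers", class = "clineshift_validation_error")
  }
  loci <- wide$locus
  n_mat <- vapply(seq_along(loci),
                  function(i) m[, wide$A[i]] + m[, wide$B[i]],
                  numeric(nrow(x)))
  n_mat <- matrix(n_mat, nrow = nrow(x))
  n_ref <- n_mat[, 1]
  if (any(n_ref < 1)) {
    abort(sprintf("population %s has N < 1 alleles sampled",
                  x$population[which(n_ref < 1)[1]]),
          class = "clineshift_validation_error")
  }
  bad <- which(n_mat != n_ref, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "A+B differs across loci: population %s, locus %s has %d alleles but locus %s has %d",
      x$population[bad[1, 1]], loci[bad[1, 2]], n_mat[bad[1, ]][1], loci[1], n_ref[bad[1, 1]]),
      class = "clineshift_validation_error")
  }
  invisible(as_tibble(x))
}

#' Per-population total number of alleles sampled
#'
#' @param counts A validated allele count table.
#' @return A tibble with columns `population` and `N`.
#' @export
allele_n <- function(counts) {
  validate_allele_counts(counts)
  info <- split_allele_names(allele_columns(counts))
  first <- info$column[info$locus == info$locus[1]]
  tibble(population = counts$population,
         N = as.integer(rowSums(counts[, first, drop = FALSE])))
}

#' Read a population allele count table
#'
#' Two dialects are supported. The `plain` dialect is a delimited table
#' (comma for `.csv`, tab otherwise) with a `population` column and paired
#' `<locus>.A` / `<locus>.B` count columns. The `genalex` dialect is a
#' GenAlEx-style codominant CSV of individual genotypes (two allele code
#' columns per locus) which is aggregated to population-level counts; allele
#' codes are mapped to A/B in sorted order per locus.
#'
#' @param path Path to the file.
#' @param dialect `"plain"` (default) or `"genalex"`.
#' @return A validated allele count tibble.
#' @export
read_allele_counts <- function(path, dialect = c("plain", "genalex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "clineshift_io_error")
  }
  if (dialect == "plain") {
    x <- reader_for(path)(path, show_col_types = FALSE)
    validate_allele_counts(x)
    return(as_tibble(x))
  }
  read_genalex_counts(path)
}

# GenAlEx-style codominant CSV:
#   line 1: n_loci, n_individuals, n_populations, <population sizes...>
#   line 2: title, ..., <population names...>
#   line 3: header: <ind id>, <pop>, locus1, , locus2, , ...
#   data : one row per individual, two allele-code cells per locus
read_genalex_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) {
    abort("GenAlEx file too short (need 3 header lines plus data)",
          class = "clineshift_format_error")
  }
  cells <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  meta <- suppressWarnings(as.integer(cells(lines[1])))
  n_loci <- meta[1]
  header <- trimws(cells(lines[3]))
  locus_names <- header[seq(3, by = 2, length.out = n_loci)]
  if (anyNA(locus_names) || any(locus_names == "")) {
    abort("GenAlEx header row 3 must name each locus in every other column from column 3",
          class = "clineshift_format_error")
  }
  rows <- lapply(lines[-(1:3)], cells)
  rows <- rows[vapply(rows, function(r) any(nzchar(trimws(r))), logical(1))]
  ind <- vapply(rows, function(r) trimws(r[1]), character(1))
  pop <- vapply(rows, function(r) trimws(r[2]), character(1))
  out <- tibble(population = unique(pop))
  for (i in seq_len(n_loci)) {
    a1 <- vapply(rows, function(r) trimws(r[2 + 2 * i - 1]), character(1))
    a2 <- vapply(rows, function(r) trimws(r[2 + 2 * i]), character(1))
    codes <- c(a1, a2)
    if (any(codes %in% c("", "0", "NA"))) {
      abort(sprintf("missing genotype at locus %s: remove incomplete individuals first",
                    locus_names[i]),
            class = "clineshift_validation_error")
    }
    lev <- sort(unique(codes))
    if (length(lev) > 2) {
      abort(sprintf("locus %s has more than two alleles (%s); only biallelic loci supported",
                    locus_names[i], paste(lev, collapse = ", ")),
            class = "clineshift_format_error")
    }
    is_a <- cbind(a1 == lev[1], a2 == lev[1])
    a_count <- vapply(unique(pop), function(p) sum(is_a[pop == p, ]), numeric(1))
    tot <- vapply(unique(pop), function(p) 2 * sum(pop == p), numeric(1))
    out[[paste0(locus_names[i], ".A")]] <- as.integer(a_count)
    out[[paste0(locus_names[i], ".B")]] <- as.integer(tot - a_count)
  }
  validate_allele_counts(out)
  out
}

#' Write a population allele count table
#'
#' Writes the canonical plain dialect (comma for `.csv`, tab otherwise).
#'
#' @param counts A validated allele count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  validate_allele_counts(counts)
  writer_for(path)(counts, path)
  invisible(path)
}

#' Read a population-by-environment table
#'
#' A delimited table with a `population` column followed by numeric
#' environmental variables (units as supplied). Missing values are rejected.
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "clineshift_io_error")
  }
  x <- reader_for(path)(path, show_col_types = FALSE)
  check_population_frame(x, "env")
  check_no_missing(x, "env")
  nonnum <- setdiff(names(x), "population")[!vapply(x[setdiff(names(x), "population")],
                                                    is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    abort(sprintf("non-numeric environmental column(s): %s", paste(nonnum, collapse = ", ")),
          class = "clineshift_format_error")
  }
  x
}

#' Read population coordinates
#'
#' @param path Path to a delimited table with columns `population`,
#'   `longitude` (decimal degrees, -180..180) and `latitude` (-90..90).
#' @return A tibble.
#' @export
read_geo_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "clineshift_io_error")
  }
  x <- reader_for(path)(path, show_col_types = FALSE)
  validate_geo_table(x)
}

#' @rdname read_geo_table
#' @param x A data frame of coordinates to validate in place.
#' @export
validate_geo_table <- function(x) {
  check_population_frame(x, "geo")
  if (!all(c("longitude", "latitude") %in% names(x))) {
    abort("geo table needs `longitude` and `latitude` columns",
          class = "clineshift_format_error")
  }
  check_no_missing(x, "geo")
  if (any(x$longitude < -180 | x$longitude > 180)) {
    abort("longitude outside [-180, 180]", class = "clineshift_validation_error")
  }
  if (any(x$latitude < -90 | x$latitude > 90)) {
    abort("latitude outside [-90, 90]", class = "clineshift_validation_error")
  }
  as_tibble(x)
}

#' Check that genetic and environmental tables are aligned
#'
#' The environmental table must list exactly the same populations in exactly
#' the same order as the genetic table: row order is part of the contract for
#' every calibration and prediction step.
#'
#' @param genetic An allele count table (or any `population`-keyed frame).
#' @param env An environment table (or any `population`-keyed frame).
#' @param error If `TRUE` (default) a mismatch aborts with a structured
#'   message naming the first divergent index; if `FALSE` the report is
#'   returned for inspection.
#' @return A tibble report with columns `index`, `genetic`, `env` and
#'   `status` (`"ok"`, `"mismatch"`, `"missing"`), invisibly when aligned.
#' @export
check_datasets <- function(genetic, env, error = TRUE) {
  check_population_frame(genetic, "genetic")
  check_population_frame(env, "env")
  g <- genetic$population
  e <- env$population
  n <- max(length(g), length(e))
  gi <- c(g, rep(NA_character_, n - length(g)))
  ei <- c(e, rep(NA_character_, n - length(e)))
  status <- dplyr::case_when(
    is.na(gi) | is.na(ei) ~ "missing",
    gi == ei ~ "ok",
    TRUE ~ "mismatch"
  )
  report <- tibble(index = seq_len(n), genetic = gi, env = ei, status = status)
  bad <- report$status != "ok"
  if (any(bad) && error) {
    first <- which(bad)[1]
    missing_pops <- setdiff(g, e)
    msg <- if (report$status[first] == "missing" || length(missing_pops) > 0) {
      sprintf("population sequences differ at index %d; missing: %s", first,
              paste(c(missing_pops, setdiff(e, g)), collapse = ", "))
    } else {
      sprintf("population sequences differ at index %d: genetic has %s, env has %s",
              first, report$genetic[first], report$env[first])
    }
    abort(msg, class = "clineshift_alignment_error", report = report)
  }
  if (any(bad)) report else invisible(report)
}

#' Identify the minor allele of each locus
#'
#' The minor allele is the allele (A or B) with the smaller total count summed
#' across all populations in the baseline data; ties are labelled A.
#'
#' @param counts An allele count table.
#' @return A tibble with columns `locus` and `minor` (`"A"` or `"B"`).
#' @export
minor_alleles <- function(counts) {
  validate_allele_counts(counts)
  loci <- locus_ids(counts)
  a_tot <- vapply(loci, function(l) sum(counts[[paste0(l, ".A")]]), numeric(1))
  b_tot <- vapply(loci, function(l) sum(counts[[paste0(l, ".B")]]), numeric(1))
  tibble(locus = unname(loci), minor = unname(ifelse(b_tot < a_tot, "B", "A")))
}

#' Convert allele counts to frequencies
#'
#' @param counts An allele count table.
#' @param which `"minor"` (default; minor allele per [minor_alleles()]),
#'   `"A"` or `"B"`.
#' @return A long tibble with columns `population`, `locus`, `allele` and
#'   `frequency` (count over the population's N, in `[0, 1]`).
#' @export
#' @examples
#' counts <- tibble::tibble(population = "Puyallup",
#'                          X01.A = 64L, X01.B = 308L)
#' counts_to_frequencies(counts)
counts_to_frequencies <- function(counts, which = c("minor", "A", "B")) {
  which <- match.arg(which)
  validate_allele_counts(counts)
  n <- allele_n(counts)$N
  minors <- minor_alleles(counts)
  purrr::map_dfr(minors$locus, function(l) {
    al <- switch(which, minor = minors$minor[minors$locus == l], which)
    freq <- counts[[paste0(l, ".", al)]] / n
    tibble(population = counts$population, locus = l, allele = al,
           frequency = freq)
  })
}

#' Validate an individual-level allele table
#'
#' A tibble with `individual`, `population` and `<locus>.A`/`<locus>.B`
#' columns; per individual and locus the two counts must sum to the ploidy.
#'
#' @param x A data frame of individual allele counts.
#' @param ploidy Ploidy (default 2, diploid).
#' @return `x` as a tibble, invisibly (errors on violation).
#' @export
validate_individuals <- function(x, ploidy = 2) {
  if (!is.data.frame(x) || !all(c("individual", "population") %in% names(x))) {
    abort("individual table needs `individual` and `population` columns",
          class = "clineshift_format_error")
  }
  if (anyDuplicated(x$individual) > 0) {
    abort("duplicated individual ids", class = "clineshift_validation_error")
  }
  check_no_missing(x, "individuals")
  cols <- setdiff(names(x), c("individual", "population"))
  info <- split_allele_names(cols)
  if (!all(info$paired_name)) {
    abort(sprintf("unpaired allele column(s): %s",
                  paste(info$column[!info$paired_name], collapse = ", ")),
          class = "clineshift_format_error")
  }
  loci <- unique(info$locus)
  for (l in loci) {
    s <- x[[paste0(l, ".A")]] + x[[paste0(l, ".B")]]
    if (any(s != ploidy)) {
      abort(sprintf("individual %s, locus %s: allele counts sum to %d, not ploidy %d",
                    x$individual[which(s != ploidy)[1]], l, s[which(s != ploidy)[1]], ploidy),
            class = "clineshift_validation_error")
    }
  }
  invisible(as_tibble(x))
}

#' Aggregate individual allele counts to population level
#'
#' The genind-to-genpop conversion contract: summing individual allele counts
#' within populations yields the population allele count table, with
#' `N = ploidy * individuals`.
#'
#' @inheritParams validate_individuals
#' @return A validated allele count tibble (populations in order of first
#'   appearance).
#' @export
aggregate_individuals <- function(x, ploidy = 2) {
  validate_individuals(x, ploidy = ploidy)
  out <- x |>
    dplyr::select(-"individual") |>
    dplyr::group_by(population = factor(.data$population, levels = unique(x$population))) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), \(v) as.integer(sum(v))),
                     .groups = "drop") |>
    dplyr::mutate(population = as.character(.data$population))
  validate_allele_counts(out)
  out
}
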