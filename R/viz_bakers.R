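# Shared helper: pick the frequency a shift visualization encodes -- the
# observed baseline frequency for baseline rows, the corrected prediction
# for changed-climate rows -- and attach the trend of the changed climate.
shift_display_data <- function(table) {
  needed <- c("population", "locus", "climate", "Allele.freq", "Freq.e2", "increasing")
  if (!all(needed %in% names(table))) {
    abort("expected a freq_pred() prediction table with baseline and changed rows",
          class = "clineshift_type_error")
  }
  if (!all(c("baseline", "changed") %in% unique(table$climate))) {
    abort("table must contain both baseline and changed climate rows",
          class = "clineshift_validation_error")
  }
  trends <- table |>
    dplyr::filter(.data$climate == "changed") |>
    dplyr::transmute(.data$population, .data$locus,
                     trend = dplyr::if_else(.data$increasing, "increasing", "decreasing"))
  out <- table |>
    dplyr::mutate(freq = dplyr::if_else(.data$climate == "baseline",
                                        .data$Allele.freq, .data$Freq.e2)) |>
    dplyr::select("population", "locus", "climate", "freq") |>
    dplyr::left_join(trends, by = c("population", "locus"))
  if (any(out$freq < 0 | out$freq > 1)) {
    bad <- out[out$freq < 0 | out$freq > 1, ][1, ]
    abort(sprintf("frequency outside [0, 1] for population %s, locus %s (%0.4f): visualizations encode corrected frequencies only",
                  bad$population, bad$locus, bad$freq),
          class = "clineshift_validation_error")
  }
  out
}

#' Prepare arc data for pie/donut shift charts
#'
#' One minor-allele arc and one complementary major-allele arc per
#' population, locus and climate. Angles are in radians measured clockwise
#' from 12 o'clock; the minor arc starts at 0 and spans `frequency * 2*pi`.
#' Baseline rows encode the observed baseline frequency, changed rows the
#' corrected prediction `Freq.e2`. Trend colors follow the convention
#' red = decreasing, green = increasing.
#'
#' @param table A [freq_pred()] prediction tibble with both climates.
#' @param r0,r1 Inner and outer ring radii (donut geometry).
#' @return A tibble: `population`, `locus`, `climate`, `allele`
#'   (`"minor"`/`"major"`), `freq`, `start`, `end`, `r0`, `r1`, `trend`.
#' @export
pie_baker <- function(table, r0 = 0.35, r1 = 1) {
  shift_display_data(table) |>
    tidyr::expand_grid(allele = c("minor", "major")) |>
    dplyr::mutate(
      start = dplyr::if_else(.data$allele == "minor", 0, 2 * pi * .data$freq),
      end = dplyr::if_else(.data$allele == "minor", 2 * pi * .data$freq, 2 * pi),
      freq = dplyr::if_else(.data$allele == "minor", .data$freq, 1 - .data$freq),
      r0 = r0, r1 = r1
    )
}

#' Prepare moon-phase data for shift charts
#'
#' The illuminated fraction of each moon equals the minor-allele frequency
#' (the complement moon carries the major allele).
#'
#' @inheritParams pie_baker
#' @return A tibble: `population`, `locus`, `climate`, `allele`, `ratio`,
#'   `trend`; minor and major ratios sum to 1.
#' @export
moon_waxer <- function(table) {
  shift_display_data(table) |>
    tidyr::expand_grid(allele = c("minor", "major")) |>
    dplyr::mutate(ratio = dplyr::if_else(.data$allele == "minor",
                                         .data$freq, 1 - .data$freq)) |>
    dplyr::select("population", "locus", "climate", "allele", "ratio", "trend")
}

#' Prepare 10x10 waffle grids for shift charts
#'
#' Each waffle has exactly 100 cells on a 10x10 grid, filled row-major from
#' the top-left; the number of minor-allele cells is the frequency times 100
#' rounded half-up.
#'
#' @inheritParams pie_baker
#' @return A tibble with 100 rows per population, locus and climate:
#'   `population`, `locus`, `climate`, `cell` (1..100), `row`, `col`,
#'   `fill` (`"minor"`/`"major"`), `trend`.
#' @export
waffle_baker <- function(table) {
  shift_display_data(table) |>
    dplyr::mutate(n_minor = round_half_up(.data$freq * 100)) |>
    tidyr::expand_grid(cell = 1:100) |>
    dplyr::mutate(
      row = (.data$cell - 1) %/% 10 + 1,
      col = (.data$cell - 1) %% 10 + 1,
      fill = dplyr::if_else(.data$cell <= .data$n_minor, "minor", "major")
    ) |>
    dplyr::select("population", "locus", "climate", "cell", "row", "col",
                  "fill", "trend")
}
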