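# polygon approximation of a donut arc; angles clockwise from 12 o'clock
arc_polygon <- function(start, end, r0, r1, n = 60) {
  th <- seq(start, end, length.out = max(2, ceiling(n * (end - start) / (2 * pi)) + 1))
  tibble(x = c(r1 * sin(th), rev(r0 * sin(th))),
         y = c(r1 * cos(th), rev(r0 * cos(th))))
}

# waxing-moon polygon: right semicircle plus terminator semi-ellipse with
# semi-axis b = 1 - 2*ratio, so the enclosed area fraction equals `ratio`
moon_polygon <- function(ratio, n = 60) {
  th <- seq(-pi / 2, pi / 2, length.out = n)
  b <- 1 - 2 * ratio
  tibble(x = c(cos(th), b * cos(rev(th))), y = c(sin(th), sin(rev(th))))
}

circle_polygon <- function(n = 90) {
  th <- seq(0, 2 * pi, length.out = n)
  tibble(x = cos(th), y = sin(th))
}

trend_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(decreasing = "red3", increasing = "green4",
               baseline = "grey30", major = "white", minor = "black"),
    name = "trend")
}

#' Plot allele-frequency shifts
#'
#' The shift-visualization suite: `"dot"` (baseline marker, changed marker
#' and a vertical confidence segment per population), `"pie"` (donut arcs),
#' `"moon"` (moon-phase glyphs) and `"waffle"` (10x10 grids). One panel per
#' locus by default; with `mean_change = TRUE` frequencies are averaged over
#' loci into a single panel. Trend colors: red = decreasing,
#' green = increasing.
#'
#' @param table A [freq_pred()] prediction tibble with both climates.
#' @param style One of `"dot"`, `"pie"`, `"moon"`, `"waffle"`.
#' @param mean_change Aggregate mean change over loci into one panel.
#' @return A ggplot object.
#' @export
shift_plot <- function(table, style = c("dot", "pie", "moon", "waffle"),
                       mean_change = FALSE) {
  style <- match.arg(style)
  if (nrow(table) == 0) abort("empty prediction table", class = "clineshift_validation_error")
  if (mean_change) {
    table <- table |>
      dplyr::group_by(.data$population, .data$climate) |>
      dplyr::summarise(dplyr::across(c("Allele.freq", "Freq.e2", "LCL", "UCL"), mean),
                       .groups = "drop") |>
      dplyr::mutate(locus = "mean over loci",
                    increasing = .data$Freq.e2 > .data$Allele.freq)
  }
  switch(style,
         dot = shift_dot_plot(table),
         pie = shift_pie_plot(table),
         moon = shift_moon_plot(table),
         waffle = shift_waffle_plot(table))
}

shift_dot_plot <- function(table) {
  base <- dplyr::filter(table, .data$climate == "baseline")
  chg <- dplyr::filter(table, .data$climate == "changed")
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$population)) +
    ggplot2::geom_segment(data = chg,
                          ggplot2::aes(xend = .data$population,
                                       y = .data$LCL, yend = .data$UCL),
                          color = "grey50") +
    ggplot2::geom_point(data = base, ggplot2::aes(y = .data$Allele.freq),
                        color = "black", size = 2) +
    ggplot2::geom_point(data = chg, ggplot2::aes(y = .data$Freq.e2),
                        color = "blue", size = 2) +
    ggplot2::facet_wrap(~locus) +
    ggplot2::labs(y = "minor allele frequency", x = NULL,
                  title = "Shift in allele frequencies (black = baseline, blue = changed)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

shift_pie_plot <- function(table) {
  arcs <- pie_baker(table)
  polys <- arcs |>
    dplyr::mutate(id = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::reframe(arc_polygon(.data$start, .data$end, .data$r0, .data$r1),
                   id = .data$id, population = .data$population,
                   locus = .data$locus, climate = .data$climate,
                   allele = .data$allele, trend = .data$trend)
  polys <- polys |>
    dplyr::mutate(fill_key = dplyr::case_when(
      allele == "major" ~ "major",
      climate == "baseline" ~ "minor",
      TRUE ~ trend))
  ggplot2::ggplot(polys, ggplot2::aes(.data$x, .data$y, group = .data$id,
                                      fill = .data$fill_key)) +
    ggplot2::geom_polygon(color = "grey40", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::facet_grid(population ~ locus + climate) +
    trend_scale() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Shift in allele frequencies (arc = minor allele share)")
}

shift_moon_plot <- function(table) {
  moons <- moon_waxer(table) |> dplyr::filter(.data$allele == "minor")
  outline <- moons |>
    dplyr::mutate(id = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::reframe(circle_polygon(), id = .data$id, population = .data$population,
                   locus = .data$locus, climate = .data$climate)
  lit <- moons |>
    dplyr::mutate(id = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::reframe(moon_polygon(.data$ratio), id = .data$id,
                   population = .data$population, locus = .data$locus,
                   climate = .data$climate, trend = .data$trend) |>
    dplyr::mutate(fill_key = dplyr::if_else(.data$climate == "baseline",
                                            "baseline", .data$trend))
  ggplot2::ggplot(mapping = ggplot2::aes(.data$x, .data$y, group = .data$id)) +
    ggplot2::geom_polygon(data = outline, fill = "white", color = "grey40",
                          linewidth = 0.2) +
    ggplot2::geom_polygon(data = lit, ggplot2::aes(fill = .data$fill_key)) +
    ggplot2::coord_equal() +
    ggplot2::facet_grid(population ~ locus + climate) +
    trend_scale() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Shift in allele frequencies (lit fraction = minor allele)")
}

shift_waffle_plot <- function(table) {
  grids <- waffle_baker(table) |>
    dplyr::mutate(fill_key = dplyr::case_when(
      fill == "major" ~ "major",
      climate == "baseline" ~ "minor",
      TRUE ~ trend))
  ggplot2::ggplot(grids, ggplot2::aes(.data$col, -.data$row, fill = .data$fill_key)) +
    ggplot2::geom_tile(color = "grey80", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::facet_grid(population ~ locus + climate) +
    trend_scale() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Shift in allele frequencies (100 cells per waffle)")
}

#' Observed-versus-predicted calibration plot
#'
#' Observed baseline minor-allele frequencies against corrected predictions,
#' split into well- and poorly-predicted population groups (see
#' [freq_scatter_data()]), with 1:1, 1:1.05 and 1:0.95 reference lines.
#'
#' @param scatter Output of [freq_scatter_data()].
#' @return A ggplot object.
#' @export
plot_freq_scatter <- function(scatter) {
  slopes <- attr(scatter, "ref_slopes") %||% c(1, 1.05, 0.95)
  ggplot2::ggplot(scatter, ggplot2::aes(.data$Freq.e2, .data$Allele.freq,
                                        color = .data$population)) +
    ggplot2::geom_abline(slope = slopes[1], intercept = 0,
                         color = "darkolivegreen", linewidth = 0.8) +
    ggplot2::geom_abline(slope = slopes[-1], intercept = 0,
                         color = "darkolivegreen", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted frequency", y = "observed frequency") +
    ggplot2::theme_minimal()
}

#' Ordination of population shifts in environmental space
#'
#' Stacks the baseline and changed climate tables and ordinates them either
#' by PCA of the standardized variables or by RDA constrained on the
#' two-level climate factor; one arrow per population runs from its baseline
#' score to its changed score.
#'
#' @param baseline,changed Aligned population-by-environment tibbles.
#' @param method `"pca"` or `"rda"`.
#' @return An object of class `population_shift`: `scores` (tibble with
#'   `population`, `climate`, `axis1`, `axis2`), `arrows` (one row per
#'   population with start and end coordinates), `method` and `plot`
#'   (a ggplot).
#' @export
population_shift_plot <- function(baseline, changed, method = c("pca", "rda")) {
  method <- match.arg(method)
  check_datasets(baseline, changed)
  vars <- setdiff(names(baseline), "population")
  if (!identical(vars, setdiff(names(changed), "population"))) {
    abort("baseline and changed tables must have identical variables",
          class = "clineshift_validation_error")
  }
  stacked <- rbind(table_matrix(baseline), table_matrix(changed))
  sds <- apply(stacked, 2, sd)
  Z <- sweep(sweep(stacked, 2, colMeans(stacked)), 2,
             ifelse(sds > 0, sds, 1), "/")
  n <- nrow(baseline)
  if (method == "pca") {
    sv <- svd(Z)
    scores2 <- Z %*% sv$v[, 1:2, drop = FALSE]
    axis_names <- c("PC1", "PC2")
  } else {
    climate_ind <- matrix(rep(c(0, 1), each = n), ncol = 1,
                          dimnames = list(NULL, "climate"))
    fit <- fit_rda(Z, climate_ind)
    Zc <- sweep(Z, 2, fit$y_means)
    ax1 <- Zc %*% fit$svd$v[, 1]
    resid <- Zc - sweep(climate_ind, 2, fit$x_means) %*% fit$coefficients
    rv <- svd(resid)
    scores2 <- cbind(ax1, resid %*% rv$v[, 1])
    axis_names <- c("RDA1", "PC1")
  }
  scores <- tibble(population = rep(baseline$population, 2),
                   climate = rep(c("baseline", "changed"), each = n),
                   axis1 = scores2[, 1], axis2 = scores2[, 2])
  arrows <- tibble(population = baseline$population,
                   x = scores2[1:n, 1], y = scores2[1:n, 2],
                   xend = scores2[n + 1:n, 1], yend = scores2[n + 1:n, 2])
  p <- ggplot2::ggplot(arrows) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          color = "steelblue") +
    ggplot2::geom_point(data = scores,
                        ggplot2::aes(.data$axis1, .data$axis2,
                                     shape = .data$climate)) +
    ggplot2::labs(x = axis_names[1], y = axis_names[2],
                  title = "Population shifts in environmental space") +
    ggplot2::theme_minimal()
  structure(list(scores = scores, arrows = arrows, method = method, plot = p),
            class = "population_shift")
}

#' @export
print.population_shift <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Smoothed geographic surface of allele frequencies
#'
#' Fits a two-dimensional penalized smooth (thin-plate by default) of
#' per-population frequencies on longitude and latitude and evaluates it on
#' a regular grid over the bounding box. With fewer than 5 locations the
#' smoother reduces to a plane. Circle sizes in the plot encode the
#' population frequencies; colors encode the trend when supplied.
#'
#' @param geo A geo tibble (`population`, `longitude`, `latitude`).
#' @param freqs Numeric vector of frequencies aligned with `geo`, or a tibble
#'   with `population` and `frequency` columns.
#' @param grid_resolution Evaluation grid is `grid_resolution` x
#'   `grid_resolution` points.
#' @param k Smooth basis dimension; default `min(10, populations - 1)`,
#'   growing with the number of locations.
#' @param bs mgcv smooth basis (`"tp"` thin-plate default, or e.g. `"ts"`).
#' @param trend Optional character vector (`"increasing"`/`"decreasing"`) per
#'   population for the circle colors.
#' @return An object of class `freq_surface`: `grid` (long tibble with
#'   `longitude`, `latitude`, `fitted`), `points`, `model`, `plot`.
#' @export
surface_fit <- function(geo, freqs, grid_resolution = 61, k = NULL,
                        bs = "tp", trend = NULL) {
  geo <- validate_geo_table(geo)
  if (is.data.frame(freqs)) {
    if (!all(c("population", "frequency") %in% names(freqs))) {
      abort("freqs data frame needs `population` and `frequency` columns",
            class = "clineshift_type_error")
    }
    freqs <- freqs$frequency[match(geo$population, freqs$population)]
  }
  n <- nrow(geo)
  if (n < 3) abort("need at least 3 population locations",
                   class = "clineshift_validation_error")
  if (qr(cbind(1, geo$longitude, geo$latitude))$rank < 3) {
    abort("population locations are collinear; a surface cannot be fitted",
          class = "clineshift_validation_error")
  }
  dat <- data.frame(f = freqs, longitude = geo$longitude, latitude = geo$latitude)
  if (n < 5) {
    model <- lm(f ~ longitude + latitude, data = dat)
  } else {
    k <- k %||% min(10, n - 1)
    k <- max(4, min(k, n - 1))
    model <- mgcv::gam(f ~ s(longitude, latitude, k = k, bs = bs), data = dat)
  }
  grid <- tidyr::expand_grid(
    longitude = seq(min(geo$longitude), max(geo$longitude),
                    length.out = grid_resolution),
    latitude = seq(min(geo$latitude), max(geo$latitude),
                   length.out = grid_resolution))
  grid$fitted <- as.numeric(predict(model, newdata = grid))
  points <- dplyr::mutate(geo, frequency = freqs,
                          trend = trend %||% NA_character_)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fitted)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$fitted), color = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "frequency") +
    ggplot2::theme_minimal()
  p <- if (is.null(trend)) {
    p + ggplot2::geom_point(data = points,
                            ggplot2::aes(size = .data$frequency),
                            shape = 21, fill = "white", color = "black")
  } else {
    p + ggplot2::geom_point(data = points,
                            ggplot2::aes(size = .data$frequency,
                                         color = .data$trend),
                            shape = 1, stroke = 1.2) +
      ggplot2::scale_color_manual(values = c(decreasing = "red3",
                                             increasing = "green4"))
  }
  structure(list(grid = grid, points = points, model = model, plot = p),
            class = "freq_surface")
}

#' @export
print.freq_surface <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Write a plot as PNG (and SVG where cairo is available)
#'
#' @param plot A ggplot object.
#' @param path_base Output path without extension.
#' @param formats Subset of `c("png", "svg")`.
#' @param width,height,dpi Device size in inches and resolution.
#' @return Character vector of files written, invisibly.
#' @export
save_shift_plot <- function(plot, path_base, formats = c("png", "svg"),
                            width = 8, height = 6, dpi = 150) {
  written <- character()
  if ("png" %in% formats) {
    f <- paste0(path_base, ".png")
    ggplot2::ggsave(f, plot, width = width, height = height, dpi = dpi,
                    device = grDevices::png)
    written <- c(written, f)
  }
  if ("svg" %in% formats) {
    if (isTRUE(unname(capabilities("cairo")))) {
      f <- paste0(path_base, ".svg")
      ggplot2::ggsave(f, plot, width = width, height = height,
                      device = grDevices::svg)
      written <- c(written, f)
    } else {
      warn("cairo not available: SVG output skipped")
    }
  }
  invisible(written)
}
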