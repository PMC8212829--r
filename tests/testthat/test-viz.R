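shift_table <- function() {
  sim <- generate_dataset(cline_scenario(n_pop = 4, n_loci = 2, seed = 22))
  predict_shifts(sim$counts, sim$env_baseline, sim$env_changed)
}

manual_table <- function(freqs_baseline, freqs_changed) {
  n <- length(freqs_baseline)
  dplyr::bind_rows(
    tibble::tibble(population = paste0("P", seq_len(n)), locus = "L1",
                   climate = "baseline", N = 100,
                   Allele.freq = freqs_baseline, A = round(100 * freqs_baseline),
                   B = 100 - round(100 * freqs_baseline),
                   Ap = 100 * freqs_baseline, Bp = 100 * (1 - freqs_baseline),
                   N.e1 = 100, Freq.e1 = freqs_baseline, Freq.e2 = freqs_baseline,
                   LCL = pmax(0, freqs_baseline - 0.05),
                   UCL = pmin(1, freqs_baseline + 0.05),
                   increasing = freqs_changed > freqs_baseline),
    tibble::tibble(population = paste0("P", seq_len(n)), locus = "L1",
                   climate = "changed", N = 100,
                   Allele.freq = freqs_baseline, A = round(100 * freqs_baseline),
                   B = 100 - round(100 * freqs_baseline),
                   Ap = 100 * freqs_changed, Bp = 100 * (1 - freqs_changed),
                   N.e1 = 100, Freq.e1 = freqs_changed, Freq.e2 = freqs_changed,
                   LCL = pmax(0, freqs_changed - 0.05),
                   UCL = pmin(1, freqs_changed + 0.05),
                   increasing = freqs_changed > freqs_baseline))
}

test_that("pie arcs span frequency times the full circle", {
  tab <- manual_table(c(0, 0.5, 0.25), c(0.1, 0.6, 0.3))
  arcs <- pie_baker(tab)
  base <- arcs[arcs$climate == "baseline" & arcs$allele == "minor", ]
  expect_equal(base$start, rep(0, 3))
  expect_equal(base$end, 2 * pi * c(0, 0.5, 0.25))
  major <- arcs[arcs$climate == "baseline" & arcs$allele == "major", ]
  expect_equal(major$end - major$start, 2 * pi * (1 - c(0, 0.5, 0.25)))
  # arcs invert exactly to the encoded frequency
  expect_equal((base$end - base$start) / (2 * pi), c(0, 0.5, 0.25))
  expect_true(all(arcs$start >= 0 & arcs$end <= 2 * pi & arcs$start <= arcs$end))
})

test_that("moons encode the frequency as the lit ratio with complement summing to 1", {
  tab <- manual_table(c(0.107, 1), c(0.2, 0.9))
  moons <- moon_waxer(tab)
  base_minor <- moons[moons$climate == "baseline" & moons$allele == "minor", ]
  expect_equal(base_minor$ratio, c(0.107, 1))
  sums <- moons |>
    dplyr::summarise(s = sum(ratio), .by = c(population, climate))
  expect_equal(sums$s, rep(1, 4))
})

test_that("waffles have exactly 100 cells with half-up rounding of minor cells", {
  tab <- manual_table(c(0.5, 0.625), c(0.4, 0.7))
  grids <- waffle_baker(tab)
  counts <- grids |>
    dplyr::summarise(cells = dplyr::n(),
                     minor = sum(fill == "minor"),
                     .by = c(population, climate))
  expect_equal(counts$cells, rep(100L, 4))
  base <- counts[order(counts$population), ]
  expect_equal(base$minor[base$climate == "baseline"], c(50, 63))
  # encoding inverts to the frequency within the 0.005 grid resolution
  expected <- dplyr::tribble(
    ~population, ~climate, ~freq,
    "P1", "baseline", 0.5, "P2", "baseline", 0.625,
    "P1", "changed", 0.4, "P2", "changed", 0.7)
  joined <- dplyr::left_join(counts, expected, by = c("population", "climate"))
  expect_true(all(abs(joined$minor / 100 - joined$freq) <= 0.005 + 1e-9))
  expect_true(all(grids$row %in% 1:10 & grids$col %in% 1:10))
})

test_that("baker transforms are pure and reject out-of-range frequencies", {
  tab <- shift_table()
  expect_identical(pie_baker(tab), pie_baker(tab))
  expect_identical(moon_waxer(tab), moon_waxer(tab))
  expect_identical(waffle_baker(tab), waffle_baker(tab))

  bad <- tab
  bad$Freq.e2[bad$climate == "changed"][1] <- 1.2
  expect_error(pie_baker(bad), class = "clineshift_validation_error")
  expect_error(waffle_baker(bad), class = "clineshift_validation_error")
})

test_that("the dot plot shows one panel per locus with all markers and intervals", {
  tab <- shift_table()
  p <- shift_plot(tab, style = "dot")
  built <- ggplot2::ggplot_build(p)
  # layer 1 = CI segments, layer 2 = baseline points, layer 3 = changed points
  expect_equal(length(unique(built$data[[2]]$PANEL)), 2)
  expect_equal(nrow(built$data[[2]]), 8)  # 4 populations x 2 loci
  expect_equal(nrow(built$data[[3]]), 8)
  expect_equal(nrow(built$data[[1]]), 8)

  p_mean <- shift_plot(tab, style = "dot", mean_change = TRUE)
  built_mean <- ggplot2::ggplot_build(p_mean)
  expect_equal(length(unique(built_mean$data[[2]]$PANEL)), 1)
  expect_equal(nrow(built_mean$data[[2]]), 4)
})

test_that("waffle plots carry the grids verbatim and empty tables error", {
  tab <- shift_table()
  p <- shift_plot(tab, style = "waffle")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), nrow(waffle_baker(tab)))
  expect_error(shift_plot(tab[0, ]), class = "clineshift_validation_error")
  # pie and moon styles build without error
  expect_s3_class(shift_plot(tab, style = "pie"), "ggplot")
  expect_s3_class(shift_plot(tab, style = "moon"), "ggplot")
})

test_that("population shift ordination draws one arrow per population", {
  env <- tiny_env()
  same <- population_shift_plot(env, env, method = "pca")
  expect_equal(nrow(same$arrows), 4)
  expect_equal(same$arrows$x, same$arrows$xend, tolerance = 1e-12)
  expect_equal(same$arrows$y, same$arrows$yend, tolerance = 1e-12)
})

test_that("a uniform climate shift gives parallel arrows under PCA", {
  env <- withr::with_seed(8, tibble::tibble(
    population = sprintf("P%02d", 1:10),
    t = rnorm(10), p = rnorm(10), s = rnorm(10)))
  changed <- dplyr::mutate(env, t = t + 1.5)
  res <- population_shift_plot(env, changed, method = "pca")
  dx <- res$arrows$xend - res$arrows$x
  dy <- res$arrows$yend - res$arrows$y
  expect_equal(diff(range(dx)), 0, tolerance = 1e-10)
  expect_equal(diff(range(dy)), 0, tolerance = 1e-10)

  rda_res <- population_shift_plot(env, changed, method = "rda")
  expect_equal(nrow(rda_res$arrows), 10)
  expect_s3_class(rda_res$plot, "ggplot")
})

test_that("surface fitting reproduces constants and planes", {
  geo <- withr::with_seed(3, tibble::tibble(
    population = sprintf("P%02d", 1:12),
    longitude = runif(12, -125, -115),
    latitude = runif(12, 42, 50)))
  const <- surface_fit(geo, rep(0.3, 12), grid_resolution = 11)
  expect_true(all(abs(const$grid$fitted - 0.3) < 1e-6))
  expect_equal(nrow(const$grid), 121)

  plane_freq <- 0.02 * (geo$latitude - 40)
  plane <- surface_fit(geo, plane_freq, grid_resolution = 9)
  oracle <- lm(f ~ longitude + latitude,
               data = data.frame(f = plane_freq, geo))
  expect_equal(plane$grid$fitted,
               unname(predict(oracle, newdata = plane$grid[1:2])),
               tolerance = 1e-4)
})

test_that("surfaces require at least 3 non-collinear locations", {
  two <- tibble::tibble(population = c("A", "B"),
                        longitude = c(0, 1), latitude = c(0, 1))
  expect_error(surface_fit(two, c(0.2, 0.4)),
               class = "clineshift_validation_error")
  collinear <- tibble::tibble(population = c("A", "B", "C", "D"),
                              longitude = 1:4, latitude = (1:4) * 2)
  expect_error(surface_fit(collinear, rep(0.5, 4)), "collinear",
               class = "clineshift_validation_error")
})

test_that("plots are written to disk as PNG", {
  tab <- shift_table()
  dir <- withr::local_tempdir()
  files <- save_shift_plot(shift_plot(tab, "dot"), file.path(dir, "dot"),
                           formats = "png", width = 4, height = 3)
  expect_true(file.exists(file.path(dir, "dot.png")))
})
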