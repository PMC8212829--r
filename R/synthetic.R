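#' Define a synthetic cline scenario
#'
#' Describes populations sampled along a climate gradient with logistic
#' allele-frequency clines: the true minor-allele frequency at locus `l` in
#' population `p` is `plogis(beta0[l] + beta1[l] * x_p)` with `x_p` the
#' driver climate variable, and the changed climate shifts every `x_p` by
#' `delta`. Observed counts are binomial draws of size `alleles_per_pop`
#' when `noise` is on, or deterministic rounded expectations when off.
#' Nuisance climate variables correlated with the driver exercise the
#' collinearity tooling.
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: 20 populations, 100 alleles sampled per population, 4 loci with
#' moderate clines across a driver spanning `[-2, 2]`, and a `+0.5` climate
#' shift (a quarter of the gradient half-width — a strong but
#' within-calibration-range displacement).
#'
#' @param n_pop Number of populations (>= 3).
#' @param n_loci Number of biallelic loci (>= 1).
#' @param alleles_per_pop Alleles sampled per population (N, >= 1).
#' @param beta0,beta1 Per-locus intercepts and slopes of the logistic clines;
#'   recycled to `n_loci`. Defaults: intercepts evenly spaced in
#'   `[-0.5, 0.5]`, slopes alternating in sign with magnitudes near 1.
#' @param x_range Range of the baseline driver variable (populations are
#'   evenly spaced across it).
#' @param delta Uniform shift of the driver in the changed climate.
#' @param noise Binomial sampling of observed counts (default `TRUE`).
#' @param n_nuisance Number of nuisance climate variables.
#' @param nuisance_cor Correlation of each nuisance variable with the driver.
#' @param seed Integer seed; all randomness is keyed by
#'   `(seed, population, locus)` counters so adding loci or nuisance
#'   variables never perturbs existing columns.
#' @return A `cline_scenario` list.
#' @export
cline_scenario <- function(n_pop = 20, n_loci = 4, alleles_per_pop = 100,
                           beta0 = NULL, beta1 = NULL,
                           x_range = c(-2, 2), delta = 0.5, noise = TRUE,
                           n_nuisance = 2, nuisance_cor = 0.7, seed = 42) {
  if (n_pop < 3) abort("need at least 3 populations", class = "clineshift_validation_error")
  if (n_loci < 1) abort("need at least 1 locus", class = "clineshift_validation_error")
  if (alleles_per_pop < 1) abort("alleles_per_pop must be >= 1",
                                 class = "clineshift_validation_error")
  # per-locus defaults cycle on the locus index alone, so extending n_loci
  # never changes the parameters of earlier loci
  idx <- seq_len(n_loci)
  beta0 <- rep_len(beta0 %||% c(-0.5, -0.25, 0, 0.25, 0.5)[(idx - 1) %% 5 + 1],
                   n_loci)
  beta1 <- rep_len(beta1 %||% (c(0.8, 0.95, 1.1, 1.25)[(idx - 1) %% 4 + 1] *
                                 (-1)^(idx - 1)), n_loci)
  structure(list(n_pop = n_pop, n_loci = n_loci, alleles_per_pop = alleles_per_pop,
                 beta0 = beta0, beta1 = beta1, x_range = x_range, delta = delta,
                 noise = noise, n_nuisance = n_nuisance,
                 nuisance_cor = nuisance_cor, seed = as.integer(seed)),
            class = "cline_scenario")
}

# deterministic stream keyed on (seed, stream id, counter); keeps columns
# stable when loci or variables are added
keyed_seed <- function(seed, stream, counter = 0) {
  v <- (as.double(seed) * 2654435761 + stream * 97561 + counter * 1013) %% 2147483647
  as.integer(v)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic dataset from a cline scenario
#'
#' @param s A [cline_scenario()].
#' @return A list with `counts` (allele count table; allele A carries the
#'   cline), `env_baseline`, `env_changed` (driver `clim1` plus nuisance
#'   variables), `geo` (populations placed along the gradient in longitude),
#'   `true_freq_baseline` and `true_freq_changed` (long tibbles with the
#'   ground-truth minor... allele-A frequencies), and the `scenario`.
#'   Reproducible: a fixed seed yields byte-identical outputs.
#' @export
#' @examples
#' sim <- generate_dataset(cline_scenario(n_pop = 6, n_loci = 2, seed = 3))
#' sim$counts
generate_dataset <- function(s) {
  if (!inherits(s, "cline_scenario")) abort("`s` must be a cline_scenario")
  g <- s$n_pop
  pops <- sprintf("P%02d", seq_len(g))
  x <- seq(s$x_range[1], s$x_range[2], length.out = g)
  counts <- tibble(population = pops)
  tf_base <- list(); tf_chg <- list()
  for (l in seq_len(s$n_loci)) {
    f_base <- plogis(s$beta0[l] + s$beta1[l] * x)
    f_chg <- plogis(s$beta0[l] + s$beta1[l] * (x + s$delta))
    a <- if (s$noise) {
      vapply(seq_len(g), function(p) {
        with_seed(keyed_seed(s$seed, l, p), rbinom(1, s$alleles_per_pop, f_base[p]))
      }, numeric(1))
    } else {
      round_half_up(s$alleles_per_pop * f_base)
    }
    locus <- sprintf("L%02d", l)
    counts[[paste0(locus, ".A")]] <- as.integer(a)
    counts[[paste0(locus, ".B")]] <- as.integer(s$alleles_per_pop - a)
    tf_base[[l]] <- tibble(population = pops, locus = locus, true_freq = f_base)
    tf_chg[[l]] <- tibble(population = pops, locus = locus, true_freq = f_chg)
  }
  env_b <- tibble(population = pops, clim1 = x)
  env_c <- tibble(population = pops, clim1 = x + s$delta)
  if (s$n_nuisance > 0) {
    x_std <- as.numeric(scale(x))
    sd_x <- sd(x)
    for (j in seq_len(s$n_nuisance)) {
      e <- with_seed(keyed_seed(s$seed, 10000 + j), rnorm(g))
      z <- s$nuisance_cor * x_std + sqrt(1 - s$nuisance_cor^2) * e
      nm <- sprintf("nuis%d", j)
      env_b[[nm]] <- z
      # the nuisance variable tracks the driver, so it shifts in proportion
      env_c[[nm]] <- z + s$nuisance_cor * s$delta / sd_x
    }
  }
  lat <- with_seed(keyed_seed(s$seed, 20000), runif(g, 40, 55))
  geo <- tibble(population = pops,
                longitude = -130 + 10 * (x - s$x_range[1]) / diff(s$x_range),
                latitude = lat)
  validate_allele_counts(counts)
  list(counts = counts,
       env_baseline = env_b,
       env_changed = env_c,
       geo = geo,
       true_freq_baseline = dplyr::bind_rows(tf_base),
       true_freq_changed = dplyr::bind_rows(tf_chg),
       scenario = s)
}

#' Generate an individual-level synthetic dataset
#'
#' Draws diploid individuals per population with per-locus allele-A dosage
#' binomial in the population's true baseline frequency. Useful for the
#' AMOVA path and for the population-centroid distance identity.
#'
#' @param s A [cline_scenario()].
#' @param ind_per_pop Individuals per population.
#' @return An individual-level allele tibble (see [validate_individuals()]).
#' @export
generate_individuals <- function(s, ind_per_pop = 10) {
  if (!inherits(s, "cline_scenario")) abort("`s` must be a cline_scenario")
  g <- s$n_pop
  pops <- sprintf("P%02d", seq_len(g))
  x <- seq(s$x_range[1], s$x_range[2], length.out = g)
  out <- tibble(individual = sprintf("I%03d", seq_len(g * ind_per_pop)),
                population = rep(pops, each = ind_per_pop))
  for (l in seq_len(s$n_loci)) {
    f <- plogis(s$beta0[l] + s$beta1[l] * x)
    dose <- unlist(lapply(seq_len(g), function(p) {
      with_seed(keyed_seed(s$seed, 30000 + l, p), rbinom(ind_per_pop, 2, f[p]))
    }))
    locus <- sprintf("L%02d", l)
    out[[paste0(locus, ".A")]] <- as.integer(dose)
    out[[paste0(locus, ".B")]] <- as.integer(2 - dose)
  }
  validate_individuals(out)
  out
}
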