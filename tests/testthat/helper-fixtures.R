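# Small in-code fixtures and independent oracles shared across tests.

tiny_counts <- function() {
  tibble::tibble(
    population = c("P1", "P2", "P3", "P4"),
    L1.A = c(3L, 6L, 9L, 12L),
    L1.B = c(17L, 14L, 11L, 8L),
    L2.A = c(15L, 12L, 8L, 5L),
    L2.B = c(5L, 8L, 12L, 15L)
  )
}

tiny_env <- function(populations = c("P1", "P2", "P3", "P4")) {
  tibble::tibble(
    population = populations,
    temp = c(10, 12, 14, 16),
    precip = c(800, 650, 500, 350)
  )
}

# brute-force AMOVA sums of squares from pairwise squared Euclidean
# distances: SS_total = sum_{i<j} d2_ij / n, SS_within summed per group
ss_pairwise <- function(Y, pops = NULL) {
  d2 <- as.matrix(stats::dist(Y))^2
  n <- nrow(Y)
  total <- sum(d2[upper.tri(d2)]) / n
  if (is.null(pops)) return(list(total = total))
  within <- 0
  for (p in unique(pops)) {
    idx <- which(pops == p)
    if (length(idx) > 1) {
      dsub <- d2[idx, idx, drop = FALSE]
      within <- within + sum(dsub[upper.tri(dsub)]) / length(idx)
    }
  }
  list(total = total, within = within, among = total - within)
}

# random individual-level allele table for AMOVA property tests
random_individuals <- function(g, ind_per_pop, n_loci, seed) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      individual = sprintf("I%03d", seq_len(g * ind_per_pop)),
      population = rep(sprintf("P%02d", seq_len(g)), each = ind_per_pop))
    for (l in seq_len(n_loci)) {
      dose <- stats::rbinom(g * ind_per_pop, 2, stats::runif(1, 0.2, 0.8))
      out[[sprintf("L%02d.A", l)]] <- as.integer(dose)
      out[[sprintf("L%02d.B", l)]] <- as.integer(2 - dose)
    }
    out
  })
}

table_matrix_for_test <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "population")])
  storage.mode(m) <- "double"
  rownames(m) <- x$population
  m
}

# minor-allele-oriented true frequencies for a generated dataset
true_minor_freqs <- function(sim, climate = c("changed", "baseline")) {
  climate <- match.arg(climate)
  truth <- if (climate == "changed") sim$true_freq_changed else sim$true_freq_baseline
  minors <- clineshift::minor_alleles(sim$counts)
  dplyr::mutate(
    dplyr::left_join(truth, minors, by = "locus"),
    true_minor = ifelse(minor == "A", true_freq, 1 - true_freq))
}
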