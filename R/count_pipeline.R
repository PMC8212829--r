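#' Calibrate the allele count model on baseline data
#'
#' First calibration step: an RDA model (or, optionally, the CCA variant)
#' with the baseline allele counts of every locus as the multivariate
#' response and the baseline climate variables as explanatory variables.
#' Reduce the climate variables with [vif_subset()] before calling this.
#'
#' @param counts Baseline allele count table.
#' @param env_baseline Baseline environment table, aligned with `counts`
#'   (checked via [check_datasets()]).
#' @param use_cca Use the canonical-correspondence-analysis variant instead
#'   of RDA (default `FALSE`).
#' @return An object of class `count_fit` holding the fitted ordination, the
#'   locus inventory with minor-allele orientation, and the baseline counts.
#' @export
#' @examples
#' sim <- generate_dataset(cline_scenario(n_pop = 10, n_loci = 2, seed = 7))
#' fit <- count_model(sim$counts, sim$env_baseline)
#' fit
count_model <- function(counts, env_baseline, use_cca = FALSE) {
  validate_allele_counts(counts)
  check_datasets(counts, env_baseline)
  check_no_missing(env_baseline, "env_baseline")
  Y <- table_matrix(counts)
  X <- table_matrix(env_baseline)
  model <- if (use_cca) fit_predict_cca(Y, X) else fit_rda(Y, X)
  structure(list(
    method = if (use_cca) "cca" else "rda",
    model = model,
    Y = Y, X = X,
    populations = counts$population,
    loci = locus_ids(counts),
    minor = minor_alleles(counts),
    N = allele_n(counts),
    counts = as_tibble(counts),
    env_names = colnames(X)
  ), class = "count_fit")
}

#' @export
print.count_fit <- function(x, ...) {
  cat("Allele count model (", toupper(x$method), "): ",
      length(x$populations), " populations, ", length(x$loci), " loci, ",
      length(x$env_names), " climate variables\n", sep = "")
  if (x$method == "rda") print(x$model)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.count_fit <- function(x, ...) {
  if (x$method == "rda") {
    dplyr::mutate(glance(x$model), method = "rda", loci = length(x$loci))
  } else {
    tibble(method = "cca", loci = length(x$loci), n = length(x$populations),
           n_negative_fitted = nrow(x$model$negative))
  }
}

#' Predict allele counts for a climate
#'
#' Second half of the first step: raw ordination predictions for each
#' population and locus are rescaled per (population, locus) pair so the two
#' predicted allele counts sum exactly to the observed number of alleles
#' sampled, `N`: `Ap = a_raw * N / (a_raw + b_raw)` (and likewise `Bp`).
#' Negative raw predictions are preserved, not clamped — mapping them back
#' into `[0, 1]` is the job of the frequency-correction step.
#'
#' @param model A `count_fit` from [count_model()].
#' @param env Environment table for the climate to predict (baseline to check
#'   the calibration, or a changed climate), aligned with the calibration
#'   populations.
#' @param climate Tag recorded in the output (`"baseline"` or `"changed"`).
#' @return A tibble with one row per population and locus: `population`,
#'   `locus`, `climate`, `N`, `A`, `B` (observed baseline counts), `Ap`,
#'   `Bp` (predicted counts, may be negative), `N.e1` (= `Ap + Bp`).
#' @export
count_pred <- function(model, env, climate = c("changed", "baseline")) {
  climate <- match.arg(climate)
  if (!inherits(model, "count_fit")) abort("`model` must come from count_model()")
  check_population_frame(env, "env")
  if (!identical(env$population, model$populations)) {
    abort("env populations differ from the calibration populations",
          class = "clineshift_alignment_error")
  }
  if (!all(model$env_names %in% names(env))) {
    abort(sprintf("env lacks model variable(s): %s",
                  paste(setdiff(model$env_names, names(env)), collapse = ", ")),
          class = "clineshift_validation_error")
  }
  X_new <- table_matrix(env[, c("population", model$env_names)])
  raw <- if (model$method == "rda") {
    predict(model$model, X_new)
  } else {
    fit_predict_cca(model$Y, model$X, X_new)$predicted
  }
  n_tbl <- model$N
  purrr::map_dfr(model$loci, function(l) {
    a_raw <- unname(raw[, paste0(l, ".A")])
    b_raw <- unname(raw[, paste0(l, ".B")])
    s <- a_raw + b_raw
    if (any(s <= 0)) {
      bad <- which(s <= 0)[1]
      abort(sprintf(
        "raw predicted counts sum to %.4f (<= 0) for population %s, locus %s: rescaling to N undefined",
        s[bad], model$populations[bad], l),
        class = "clineshift_prediction_error")
    }
    tibble(population = model$populations,
           locus = l,
           climate = climate,
           N = n_tbl$N,
           A = as.integer(model$counts[[paste0(l, ".A")]]),
           B = as.integer(model$counts[[paste0(l, ".B")]]),
           Ap = a_raw * n_tbl$N / s,
           Bp = b_raw * n_tbl$N / s,
           N.e1 = a_raw * n_tbl$N / s + b_raw * n_tbl$N / s)
  })
}
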