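#' Calibrate the frequency-correction models
#'
#' Second calibration step: for each locus, a binomial smooth model (logit
#' link) of the observed baseline minor-allele frequency — as a
#' successes/failures response, so populations are weighted by their sample
#' size N — on the RDA-predicted baseline count of the minor allele. The
#' smooth is a penalized cubic regression spline fitted with [mgcv::gam()];
#' because the inverse link is the logistic function, every prediction from
#' this step lies in (0, 1) regardless of how far the raw count predictions
#' stray.
#'
#' @param counts Baseline allele count table (the calibration response).
#' @param baseline_pred A [count_pred()] table computed with the *baseline*
#'   environment (`climate = "baseline"`), i.e. the calibration check.
#' @param basis_dim Spline basis dimension per locus. Default
#'   `min(4, populations - 1)`; a small basis guards against overfitting the
#'   handful of populations typical of these designs. Values below 3 fit a
#'   linear-in-link (ordinary logistic) model; values exceeding
#'   `populations - 1` are reduced with a warning.
#' @return An object of class `freq_fit`: per-locus fitted models plus the
#'   minor-allele orientation used.
#' @export
freq_model <- function(counts, baseline_pred, basis_dim = NULL) {
  validate_allele_counts(counts)
  if (!all(c("population", "locus", "Ap", "Bp") %in% names(baseline_pred))) {
    abort("`baseline_pred` must be a count_pred() table", class = "clineshift_type_error")
  }
  if ("climate" %in% names(baseline_pred) && any(baseline_pred$climate != "baseline")) {
    abort("`baseline_pred` must be computed for the baseline climate",
          class = "clineshift_validation_error")
  }
  n_pop <- nrow(counts)
  minors <- minor_alleles(counts)
  n_tbl <- allele_n(counts)
  k <- basis_dim %||% min(4, n_pop - 1)
  if (k > n_pop - 1) {
    warn(sprintf("basis_dim %d exceeds populations - 1; reduced to %d", k, n_pop - 1))
    k <- n_pop - 1
  }
  models <- purrr::map(minors$locus, function(l) {
    m <- minors$minor[minors$locus == l]
    a <- counts[[paste0(l, ".", m)]]
    b <- n_tbl$N - a
    pl <- baseline_pred[baseline_pred$locus == l, ]
    pl <- pl[match(counts$population, pl$population), ]
    x <- if (m == "A") pl$Ap else pl$Bp
    if (all(a == 0) || all(b == 0)) {
      warn(sprintf("locus %s: all baseline frequencies are %d; fitted constant",
                   l, as.integer(all(b == 0))))
      return(list(type = "constant", value = as.numeric(all(b == 0))))
    }
    dat <- data.frame(a = a, b = b, x = x)
    fit <- if (k >= 3 && sd(x) > 0) {
      mgcv::gam(cbind(a, b) ~ s(x, k = k, bs = "cr"), family = binomial, data = dat)
    } else if (sd(x) > 0) {
      mgcv::gam(cbind(a, b) ~ x, family = binomial, data = dat)
    } else {
      mgcv::gam(cbind(a, b) ~ 1, family = binomial, data = dat)
    }
    list(type = "gam", fit = fit)
  })
  names(models) <- minors$locus
  structure(list(models = models, minor = minors, basis_dim = k,
                 populations = counts$population, loci = minors$locus),
            class = "freq_fit")
}

#' @export
print.freq_fit <- function(x, ...) {
  cat("Frequency-correction models:", length(x$loci), "loci, basis dimension",
      x$basis_dim, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.freq_fit <- function(x, ...) {
  purrr::map_dfr(x$loci, function(l) {
    m <- x$models[[l]]
    if (m$type == "constant") {
      return(tibble(locus = l, term = "(constant)", estimate = qlogis(m$value),
                    edf = NA_real_))
    }
    sm <- summary(m$fit)
    tibble(locus = l,
           term = rownames(sm$p.table) %||% "(Intercept)",
           estimate = sm$p.table[, 1],
           edf = if (length(sm$edf)) sum(sm$edf) else 0)
  })
}

# link-scale prediction with standard errors, handling degenerate fits
freq_link_predict <- function(model, x) {
  if (model$type == "constant") {
    return(list(fit = rep(qlogis(pmin(pmax(model$value, 0), 1)), length(x)),
                se = rep(0, length(x)), constant = model$value))
  }
  p <- predict(model$fit, newdata = data.frame(x = x), type = "link", se.fit = TRUE)
  list(fit = as.numeric(p$fit), se = as.numeric(p$se.fit), constant = NULL)
}

#' Predict corrected allele frequencies
#'
#' Second prediction step: maps the (possibly negative) RDA-predicted minor
#' allele counts onto valid frequencies through the per-locus binomial smooth
#' models, with 95% confidence limits computed on the link scale and
#' back-transformed (so limits are guaranteed to lie in `[0, 1]`).
#'
#' @param fm A `freq_fit` from [freq_model()].
#' @param pred A [count_pred()] table for the climate of interest.
#' @return A prediction tibble with one row per population and locus and the
#'   standard output schema: `population`, `locus`, `climate`, `N`,
#'   `Allele.freq` (observed baseline minor-allele frequency), `A`, `B`
#'   (observed baseline minor/major counts), `Ap`, `Bp` (predicted
#'   minor/major counts), `N.e1` (= `Ap + Bp`), `Freq.e1` (= `Ap / N.e1`,
#'   may fall outside `[0, 1]`), `Freq.e2` (corrected frequency in `[0, 1]`),
#'   `LCL`, `UCL` (95% limits) and `increasing` (`Freq.e2 > Allele.freq`).
#' @export
freq_pred <- function(fm, pred) {
  if (!inherits(fm, "freq_fit")) abort("`fm` must come from freq_model()")
  missing_loci <- setdiff(unique(pred$locus), fm$loci)
  if (length(missing_loci) > 0) {
    abort(sprintf("locus absent from the frequency model: %s",
                  paste(missing_loci, collapse = ", ")),
          class = "clineshift_validation_error")
  }
  z <- qnorm(0.975)
  purrr::map_dfr(intersect(fm$loci, unique(pred$locus)), function(l) {
    m <- fm$minor$minor[fm$minor$locus == l]
    pl <- pred[pred$locus == l, ]
    # orient all counts to minor allele first
    a_obs <- if (m == "A") pl$A else pl$B
    b_obs <- if (m == "A") pl$B else pl$A
    ap <- if (m == "A") pl$Ap else pl$Bp
    bp <- if (m == "A") pl$Bp else pl$Ap
    lk <- freq_link_predict(fm$models[[l]], ap)
    f2 <- plogis(lk$fit)
    lcl <- plogis(lk$fit - z * lk$se)
    ucl <- plogis(lk$fit + z * lk$se)
    if (!is.null(lk$constant)) {
      f2 <- rep(lk$constant, nrow(pl)); lcl <- f2; ucl <- f2
    }
    tibble(population = pl$population,
           locus = l,
           climate = pl$climate %||% NA_character_,
           N = pl$N,
           Allele.freq = a_obs / pl$N,
           A = a_obs, B = b_obs,
           Ap = ap, Bp = bp,
           N.e1 = pl$N.e1,
           Freq.e1 = ap / pl$N.e1,
           Freq.e2 = f2,
           LCL = lcl, UCL = ucl,
           increasing = f2 > a_obs / pl$N)
  })
}

#' Run the full two-step shift prediction
#'
#' Convenience pipeline: calibrate the count model on the baseline data,
#' check the calibration by predicting the baseline climate, calibrate the
#' frequency-correction models, and predict corrected frequencies for both
#' climates.
#'
#' @inheritParams count_model
#' @param env_changed Changed-climate environment table, aligned with
#'   `counts`.
#' @inheritParams freq_model
#' @return A prediction tibble (see [freq_pred()]) with both `"baseline"` and
#'   `"changed"` rows, carrying the fitted `count_fit` and `freq_fit` in
#'   attributes `"count_fit"` and `"freq_fit"`.
#' @export
#' @examples
#' sim <- generate_dataset(cline_scenario(n_pop = 12, n_loci = 2, seed = 1))
#' shifts <- predict_shifts(sim$counts, sim$env_baseline, sim$env_changed)
#' dplyr::glimpse(shifts)
predict_shifts <- function(counts, env_baseline, env_changed,
                           use_cca = FALSE, basis_dim = NULL) {
  fit <- count_model(counts, env_baseline, use_cca = use_cca)
  base_pred <- count_pred(fit, env_baseline, climate = "baseline")
  fm <- freq_model(counts, base_pred, basis_dim = basis_dim)
  changed_pred <- count_pred(fit, env_changed, climate = "changed")
  out <- dplyr::bind_rows(freq_pred(fm, base_pred), freq_pred(fm, changed_pred))
  attr(out, "count_fit") <- fit
  attr(out, "freq_fit") <- fm
  out
}

#' Split populations by goodness of fit of the calibration
#'
#' For each population, the share of variance in observed baseline
#' frequencies explained by the corrected predictions across loci (squared
#' Pearson correlation of `Allele.freq` on `Freq.e2`). Populations are
#' partitioned at `r2_split` into well-predicted (`"high"`) and poorly
#' predicted (`"low"`) groups for observed-versus-predicted plotting against
#' 1:1, 1:1.05 and 1:0.95 reference lines.
#'
#' @param table A baseline-climate prediction tibble from [freq_pred()].
#' @param r2_split R-squared split point (default 0.5).
#' @return The prediction rows joined with per-population `r2` and `group`,
#'   with attribute `ref_slopes = c(1, 1.05, 0.95)`.
#' @export
freq_scatter_data <- function(table, r2_split = 0.5) {
  stats <- table |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      r2 = {
        if (dplyr::n() < 3) NA_real_
        else if (sd(.data$Allele.freq) == 0 || sd(.data$Freq.e2) == 0) 0
        else cor(.data$Allele.freq, .data$Freq.e2)^2
      },
      .groups = "drop")
  if (anyNA(stats$r2)) {
    warn("populations with fewer than 3 loci have undefined R-squared; placed in the low group")
  }
  out <- table |>
    dplyr::left_join(stats, by = "population") |>
    dplyr::mutate(group = dplyr::if_else(!is.na(.data$r2) & .data$r2 > r2_split,
                                         "high", "low"))
  attr(out, "ref_slopes") <- c(1, 1.05, 0.95)
  out
}
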