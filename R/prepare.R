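#' Variance inflation factors of environmental variables
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the ordinary least-squares
#' regression (with intercept) of variable j on all other variables. A single
#' variable has VIF 1; a perfectly collinear variable is reported as `Inf`.
#'
#' @param env A population-by-environment tibble (leading `population`
#'   column; at least 2 rows).
#' @return A tibble with columns `variable` and `vif`, in input column order.
#' @export
#' @examples
#' env <- tibble::tibble(population = c("P1", "P2", "P3", "P4"),
#'                       t = c(1, 2, 3, 4), p = c(4, 2, 3, 1))
#' compute_vif(env)
compute_vif <- function(env) {
  check_population_frame(env, "env")
  check_no_missing(env, "env")
  m <- table_matrix(env)
  if (ncol(m) == 0) return(tibble(variable = character(), vif = numeric()))
  if (nrow(m) < 2) abort("need at least 2 populations", class = "clineshift_validation_error")
  vars <- colnames(m)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance variable: %s", vars[which(sds == 0)[1]]),
          class = "clineshift_validation_error")
  }
  vifs <- vapply(seq_along(vars), function(j) {
    if (length(vars) == 1) return(1)
    y <- m[, j]
    x <- cbind(1, m[, -j, drop = FALSE])
    fit <- lm.fit(x, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(variable = vars, vif = vifs)
}

#' Reduce environmental variables by variance inflation factor
#'
#' Two-step reduction. Step 1 removes every non-`keep` variable whose absolute
#' Pearson correlation with any `keep` variable exceeds `cor_cut`. Step 2
#' iteratively removes the non-`keep` variable with the largest VIF until all
#' non-`keep` VIFs are at or below `threshold` (ties broken by column order;
#' first wins removal). Variables in `keep` are always retained.
#'
#' @inheritParams compute_vif
#' @param threshold Maximum acceptable VIF for retained variables (default 20,
#'   the usual working ceiling for collinearity in this setting).
#' @param keep Character vector of variables to force-retain.
#' @param cor_cut Absolute-correlation cutoff against `keep` variables for
#'   step 1 (default 0.9).
#' @return An object of class `vif_report`: list with `retained` (character),
#'   `dropped` (tibble: `variable`, `vif`, `step`), `final_vifs` (tibble),
#'   `threshold`, `cor_cut`, `keep`. Has [tidy()] and [glance()] methods.
#' @export
vif_subset <- function(env, threshold = 20, keep = character(), cor_cut = 0.9) {
  check_population_frame(env, "env")
  vars <- setdiff(names(env), "population")
  if (!all(keep %in% vars)) {
    abort(sprintf("keep variable(s) not in env: %s",
                  paste(setdiff(keep, vars), collapse = ", ")),
          class = "clineshift_validation_error")
  }
  dropped <- tibble(variable = character(), vif = numeric(), step = character())
  current <- vars

  if (length(keep) > 1) {
    keep_v <- compute_vif(env[, c("population", keep)])
    if (any(!is.finite(keep_v$vif))) {
      warn("keep variables are mutually collinear; retained regardless")
    }
  }

  # step 1: drop non-keep variables too correlated with any keep variable
  if (length(keep) > 0) {
    cm <- cor(table_matrix(env[, c("population", current)]))
    for (v in setdiff(current, keep)) {
      if (max(abs(cm[v, keep])) > cor_cut) {
        vif_now <- compute_vif(env[, c("population", current)])
        dropped <- dplyr::bind_rows(dropped, tibble(
          variable = v, vif = vif_now$vif[vif_now$variable == v], step = "correlation"))
        current <- setdiff(current, v)
      }
    }
  }

  # step 2: iterative removal of the worst non-keep VIF
  repeat {
    vifs <- compute_vif(env[, c("population", current), drop = FALSE])
    cand <- vifs[!(vifs$variable %in% keep), , drop = FALSE]
    if (nrow(cand) == 0 || all(cand$vif <= threshold)) break
    worst <- cand$variable[which.max(cand$vif)]  # which.max: first max wins
    dropped <- dplyr::bind_rows(dropped, tibble(
      variable = worst, vif = cand$vif[cand$variable == worst], step = "vif"))
    current <- setdiff(current, worst)
    if (length(current) == 0) break
  }

  structure(list(
    retained = current,
    dropped = dropped,
    final_vifs = compute_vif(env[, c("population", current), drop = FALSE]),
    threshold = threshold,
    cor_cut = cor_cut,
    keep = keep
  ), class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF subset (threshold ", x$threshold, ", cor_cut ", x$cor_cut, ")\n", sep = "")
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0) {
    cat("dropped:\n")
    print(x$dropped)
  } else {
    cat("dropped: none\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vif_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$final_vifs, status = "retained", step = NA_character_),
    dplyr::mutate(x$dropped, status = "dropped")
  )
}

#' @exportS3Method generics::glance
glance.vif_report <- function(x, ...) {
  tibble(n_retained = length(x$retained),
         n_dropped = nrow(x$dropped),
         max_vif = max(x$final_vifs$vif),
         threshold = x$threshold,
         cor_cut = x$cor_cut)
}

#' Flag populations facing novel climates
#'
#' A changed-climate value is novel when it falls strictly outside the
#' baseline range of that variable across all populations (the calibration
#' range; boundary values are not novel). Each novel value is scored with a
#' one-sided normal tail probability computed from the baseline column mean
#' and sample standard deviation: `1 - pnorm((x - mu)/sigma)` above the range,
#' `pnorm((x - mu)/sigma)` below it. A population's `novelty_p` is the
#' minimum tail probability across its flagged variables — the degree of
#' novelty of its changed conditions.
#'
#' @param baseline,changed Aligned population-by-environment tibbles with
#'   identical variables.
#' @return A tibble with one row per flagged population-variable pair:
#'   `population`, `variable`, `changed_value`, `baseline_min`,
#'   `baseline_max`, `baseline_mean`, `baseline_sd`, `p`, `novelty_p`.
#'   Populations with no novel variable are absent.
#' @export
environmental_novel <- function(baseline, changed) {
  check_datasets(baseline, changed)
  vars <- setdiff(names(baseline), "population")
  if (!identical(vars, setdiff(names(changed), "population"))) {
    abort("baseline and changed tables must have identical variables",
          class = "clineshift_validation_error")
  }
  check_no_missing(baseline, "baseline"); check_no_missing(changed, "changed")
  rows <- purrr::map_dfr(vars, function(v) {
    b <- baseline[[v]]
    x <- changed[[v]]
    lo <- min(b); hi <- max(b); mu <- mean(b); sg <- sd(b)
    out <- which(x < lo | x > hi)
    if (length(out) == 0) return(tibble())
    p <- vapply(out, function(i) {
      if (sg == 0) {
        warn(sprintf("variable %s has zero baseline standard deviation; novelty probability reported as 0", v))
        return(0)
      }
      z <- (x[i] - mu) / sg
      if (x[i] > hi) 1 - pnorm(z) else pnorm(z)
    }, numeric(1))
    tibble(population = baseline$population[out], variable = v,
           changed_value = x[out], baseline_min = lo, baseline_max = hi,
           baseline_mean = mu, baseline_sd = sg, p = p)
  })
  if (nrow(rows) == 0) {
    return(tibble(population = character(), variable = character(),
                  changed_value = numeric(), baseline_min = numeric(),
                  baseline_max = numeric(), baseline_mean = numeric(),
                  baseline_sd = numeric(), p = numeric(), novelty_p = numeric()))
  }
  rows |>
    dplyr::mutate(population = factor(.data$population, levels = baseline$population)) |>
    dplyr::arrange(.data$population) |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(novelty_p = min(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(population = as.character(.data$population))
}
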