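#' Fit a redundancy analysis (RDA) model
#'
#' RDA is the principal components analysis of the fitted values from the
#' multivariate least-squares regression of a (column-centered) response
#' matrix on (column-centered) explanatory variables; it preserves Euclidean
#' distances among rows. Inertia is scaled by `n - 1` (variance convention),
#' so sums of squares are recovered as inertia times `n - 1`.
#'
#' With a zero-column `X` the model degenerates to an unconstrained PCA of
#' the centered response (all inertia "constrained" by the empty model).
#'
#' @param Y Numeric response matrix or data frame (rows = populations or
#'   individuals, columns = alleles or any responses).
#' @param X Numeric explanatory matrix or data frame, row-aligned with `Y`.
#' @return An object of class `rda_fit`: centering vectors, the coefficient
#'   matrix `B`, the SVD of the fitted matrix, and the variance
#'   decomposition (`total_inertia`, `constrained_inertia`,
#'   `residual_inertia`). Supports [predict()], [tidy()] and [glance()].
#' @export
#' @examples
#' Y <- matrix(rnorm(18), 6, 3)
#' X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("t", "p")))
#' fit <- fit_rda(Y, X)
#' glance(fit)
fit_rda <- function(Y, X) {
  Y <- as.matrix(Y); storage.mode(Y) <- "double"
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (nrow(Y) != nrow(X)) abort("Y and X must have the same rows",
                                class = "clineshift_validation_error")
  n <- nrow(Y)
  if (is.null(colnames(X)) && ncol(X) > 0) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  y_means <- colMeans(Y)
  x_means <- colMeans(X)
  Yc <- sweep(Y, 2, y_means)
  if (ncol(X) > 0) {
    Xc <- sweep(X, 2, x_means)
    qx <- qr(Xc)
    if (qx$rank < ncol(Xc)) {
      dep <- colnames(Xc)[qx$pivot[(qx$rank + 1):ncol(Xc)]]
      abort(sprintf("explanatory matrix is rank-deficient; dependent column(s): %s",
                    paste(dep, collapse = ", ")),
            class = "clineshift_rank_error")
    }
    if (n <= ncol(Xc)) {
      abort("need more rows than explanatory columns", class = "clineshift_validation_error")
    }
    B <- qr.coef(qx, Yc)
    Fhat <- Xc %*% B
  } else {
    B <- matrix(0, 0, ncol(Y), dimnames = list(NULL, colnames(Y)))
    Fhat <- Yc
  }
  sv <- svd(Fhat)
  keep <- sv$d > max(sv$d[1], 0) * 1e-10
  total <- sum(Yc^2) / (n - 1)
  constrained <- sum(Fhat^2) / (n - 1)
  structure(list(
    y_means = y_means, x_means = x_means, coefficients = B,
    svd = list(u = sv$u[, keep, drop = FALSE],
               d = sv$d[keep],
               v = sv$v[, keep, drop = FALSE]),
    total_inertia = total,
    constrained_inertia = constrained,
    residual_inertia = sum((Yc - Fhat)^2) / (n - 1),
    n = n,
    x_names = colnames(X), y_names = colnames(Y)
  ), class = "rda_fit")
}

#' Predict responses from a fitted RDA model
#'
#' `Yhat = (X_new - x_means) %*% B + y_means`, optionally projected onto the
#' leading constrained axes before un-centering.
#'
#' @param object An `rda_fit`.
#' @param newdata Explanatory matrix or data frame with the model's variables
#'   in order (a `population` column, if present, is ignored).
#' @param rank `"full"` (default) or an integer number of constrained axes to
#'   retain.
#' @param ... Unused.
#' @return The predicted response matrix.
#' @export
predict.rda_fit <- function(object, newdata, rank = "full", ...) {
  if (is.data.frame(newdata)) {
    newdata <- newdata[, setdiff(names(newdata), "population"), drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  if (length(object$x_names) > 0) {
    if (!is.null(colnames(newdata))) {
      if (!all(object$x_names %in% colnames(newdata))) {
        abort(sprintf("newdata lacks model variable(s): %s",
                      paste(setdiff(object$x_names, colnames(newdata)), collapse = ", ")),
              class = "clineshift_validation_error")
      }
      newdata <- newdata[, object$x_names, drop = FALSE]
    } else if (ncol(newdata) != length(object$x_names)) {
      abort("newdata has the wrong number of columns", class = "clineshift_validation_error")
    }
  }
  Fn <- sweep(newdata, 2, object$x_means) %*% object$coefficients
  if (!identical(rank, "full")) {
    r <- min(as.integer(rank), length(object$svd$d))
    V <- object$svd$v[, seq_len(r), drop = FALSE]
    Fn <- Fn %*% V %*% t(V)
  }
  sweep(Fn, 2, object$y_means, "+")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("RDA fit:", length(x$y_names), "responses,", length(x$x_names),
      "explanatory variables,", x$n, "rows\n")
  cat(sprintf("inertia: total %.4f, constrained %.4f (%.1f%%)\n",
              x$total_inertia, x$constrained_inertia,
              100 * x$constrained_inertia / x$total_inertia))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rda_fit <- function(x, ...) {
  eig <- x$svd$d^2 / (x$n - 1)
  tibble(axis = paste0("RDA", seq_along(eig)),
         eigenvalue = eig,
         prop_constrained = eig / sum(eig),
         prop_total = eig / x$total_inertia)
}

#' @exportS3Method generics::glance
glance.rda_fit <- function(x, ...) {
  tibble(total_inertia = x$total_inertia,
         constrained_inertia = x$constrained_inertia,
         residual_inertia = x$residual_inertia,
         prop_constrained = x$constrained_inertia / x$total_inertia,
         rank = length(x$svd$d),
         n = x$n)
}

# Weighted standardization stats used by the CCA variant.
cca_standardize <- function(X, w, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colSums(X * w)
  Xc <- sweep(X, 2, center)
  if (is.null(scale)) scale <- sqrt(colSums(Xc^2 * w))
  if (any(scale == 0)) abort("constant explanatory column in CCA fit",
                             class = "clineshift_validation_error")
  list(Xs = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}

#' Canonical correspondence analysis fit and count prediction
#'
#' The CCA alternative to the RDA count model: the response is converted to
#' chi-square-standardized profiles `Q = (P - r c') / sqrt(r c')` (with `P`
#' the table divided by its grand total and `r`, `c` the row and column
#' masses), `Q` is regressed on row-weight-standardized explanatory variables
#' by weighted least squares, and fitted profiles are back-transformed to
#' expected counts at the calibration row and column masses. Predicted counts
#' can be negative; such cells are flagged.
#'
#' @param Y Nonnegative count matrix (positive row and column sums).
#' @param X Explanatory matrix/data frame, row-aligned with `Y`.
#' @param X_new Explanatory data for prediction (defaults to `X`).
#' @return A list with `predicted` (matrix of expected counts for `X_new`
#'   rows at calibration masses), `negative` (tibble of flagged cells) and
#'   `fitted_q` (fitted standardized profiles).
#' @export
fit_predict_cca <- function(Y, X, X_new = NULL) {
  Y <- as.matrix(Y); storage.mode(Y) <- "double"
  if (is.data.frame(X)) X <- as.matrix(X[, setdiff(colnames(X), "population"), drop = FALSE])
  if (is.null(X_new)) X_new <- X
  if (is.data.frame(X_new)) {
    X_new <- as.matrix(X_new[, setdiff(colnames(X_new), "population"), drop = FALSE])
  }
  if (any(rowSums(Y) <= 0) || any(colSums(Y) <= 0)) {
    abort("CCA needs positive row and column sums", class = "clineshift_validation_error")
  }
  if (nrow(X_new) != nrow(Y)) {
    abort("X_new must have one row per calibration population (predictions are made at the calibration row masses)",
          class = "clineshift_validation_error")
  }
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  Q <- (P - E) / sqrt(E)
  std <- cca_standardize(X, r)
  Xw <- cbind(intercept = sqrt(r), sqrt(r) * std$Xs)
  fit <- lm.fit(Xw, Q)
  Bw <- fit$coefficients
  Xs_new <- cca_standardize(X_new, r, center = std$center, scale = std$scale)$Xs
  Qhat_new <- (cbind(intercept = sqrt(r), sqrt(r) * Xs_new)) %*% Bw
  pred <- (Qhat_new * sqrt(E) + E) * tot
  dimnames(pred) <- dimnames(Y)
  neg <- which(pred < 0, arr.ind = TRUE)
  negative <- tibble(
    row = if (nrow(neg)) rownames(pred)[neg[, 1]] %||% as.character(neg[, 1]) else character(),
    column = if (nrow(neg)) colnames(pred)[neg[, 2]] %||% as.character(neg[, 2]) else character(),
    value = pred[neg]
  )
  if (nrow(negative) > 0) {
    warn(sprintf("CCA predicted %d negative count(s); the frequency-correction step maps these back into [0, 1]",
                 nrow(negative)))
  }
  list(predicted = pred, negative = negative, fitted_q = Xw %*% Bw,
       row_mass = r, col_mass = cc, total = tot,
       coefficients = Bw, x_center = std$center, x_scale = std$scale)
}

#' AMOVA from the RDA decomposition
#'
#' Analysis of molecular variance computed from the redundancy-analysis
#' variance decomposition: individuals-by-alleles counts are regressed on
#' population indicator variables; the constrained sum of squares is the
#' among-population SS and the residual sum of squares the within-population
#' SS (the partition of pairwise squared Euclidean distances). Variance
#' components and Phi_ST follow the standard one-level AMOVA estimators with
#' `n0` the weighted average sample size.
#'
#' @param individuals An individual-level allele table (see
#'   [validate_individuals()]).
#' @param ploidy Ploidy (default 2).
#' @return An object of class `amova_table`: `table` (tibble with `source`,
#'   `df`, `SS`, `MS`), `sigma2` (tibble with variance components and percent
#'   of total), `phi_st`, `n0`. Has [tidy()] and [glance()] methods.
#' @export
amova_rda <- function(individuals, ploidy = 2) {
  validate_individuals(individuals, ploidy = ploidy)
  pops <- individuals$population
  g <- length(unique(pops))
  n <- nrow(individuals)
  if (g < 2) abort("AMOVA needs at least 2 populations", class = "clineshift_validation_error")
  if (n <= g) abort("AMOVA needs more individuals than populations",
                    class = "clineshift_validation_error")
  Y <- table_matrix(individuals, id_cols = c("individual", "population"))
  X <- model.matrix(~ factor(pops, levels = unique(pops)))[, -1, drop = FALSE]
  fit <- fit_rda(Y, X)
  ss_among <- fit$constrained_inertia * (n - 1)
  ss_within <- fit$residual_inertia * (n - 1)
  ss_total <- ss_among + ss_within
  df <- c(g - 1, n - g, n - 1)
  ss <- c(ss_among, ss_within, ss_total)
  ms <- ss / df
  sizes <- as.numeric(table(pops))
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  s2_within <- ms[2]
  s2_among <- (ms[1] - ms[2]) / n0
  if (ss_total <= 1e-12) {
    warn("all individuals identical: variance components are zero and Phi_ST is undefined")
    phi <- NA_real_
    s2_among <- 0; s2_within <- 0
  } else {
    phi <- s2_among / (s2_among + s2_within)
  }
  structure(list(
    table = tibble(source = c("Among populations", "Within populations", "Total"),
                   df = df, SS = ss, MS = ms),
    sigma2 = tibble(source = c("Among populations", "Within populations"),
                    variance = c(s2_among, s2_within),
                    percent = if (s2_among + s2_within > 0)
                      100 * c(s2_among, s2_within) / (s2_among + s2_within)
                    else c(NA_real_, NA_real_)),
    phi_st = phi, n0 = n0, n = n, g = g
  ), class = "amova_table")
}

#' @export
print.amova_table <- function(x, ...) {
  cat("AMOVA (", x$g, "populations,", x$n, "individuals )\n")
  print(as.data.frame(x$table), row.names = FALSE)
  print(as.data.frame(x$sigma2), row.names = FALSE)
  cat(sprintf("Phi_ST = %s (n0 = %.4f)\n",
              ifelse(is.na(x$phi_st), "NA", sprintf("%.4f", x$phi_st)), x$n0))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.amova_table <- function(x, ...) {
  dplyr::left_join(x$table, x$sigma2, by = "source")
}

#' @exportS3Method generics::glance
glance.amova_table <- function(x, ...) {
  tibble(phi_st = x$phi_st, n0 = x$n0, n = x$n, g = x$g,
         ss_total = x$table$SS[3])
}

#' Serialize an AMOVA table to delimited text
#'
#' @param x An `amova_table`.
#' @param path Output path (comma for `.csv`, tab otherwise).
#' @return `path`, invisibly.
#' @export
write_amova <- function(x, path) {
  out <- tidy(x) |>
    dplyr::mutate(phi_st = c(x$phi_st, NA_real_, NA_real_))
  writer_for(path)(out, path)
  invisible(path)
}
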