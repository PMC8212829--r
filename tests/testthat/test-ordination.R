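test_that("perfect linear dependence puts all inertia in the constrained part", {
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  y <- 2 * x
  fit <- fit_rda(y, x)
  expect_equal(fit$constrained_inertia, fit$total_inertia)
  yc <- sweep(y, 2, colMeans(y))
  expect_equal(predict(fit, x), y, ignore_attr = TRUE)
  expect_equal(sweep(predict(fit, x), 2, fit$y_means), yc, ignore_attr = TRUE)
})

test_that("responses orthogonal to the constraints give zero constrained inertia", {
  x <- matrix(c(-1, 0, 1), ncol = 1)
  y <- matrix(c(1, -2, 1), ncol = 1)  # zero covariance with x
  fit <- fit_rda(y, x)
  expect_equal(unname(fit$coefficients[1, 1]), 0)
  expect_equal(fit$constrained_inertia, 0)
})

test_that("coefficients match a normal-equations oracle and singular values carry the inertia", {
  set.seed(5)
  y <- matrix(rnorm(18), 6, 3)
  x <- matrix(rnorm(12), 6, 2)
  fit <- fit_rda(y, x)
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  b_oracle <- solve(t(xc) %*% xc, t(xc) %*% yc)
  expect_equal(unname(fit$coefficients), unname(b_oracle), tolerance = 1e-10)
  expect_equal(sum(fit$svd$d^2) / (nrow(y) - 1), fit$constrained_inertia,
               tolerance = 1e-12)
  # conservation of variance
  expect_equal(fit$constrained_inertia + fit$residual_inertia,
               fit$total_inertia, tolerance = 1e-12)
})

test_that("inertia decomposition agrees with an independent RDA implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  y <- matrix(rpois(60, 20), 10, 6)
  x <- data.frame(t = rnorm(10), p = rnorm(10))
  fit <- fit_rda(y, as.matrix(x))
  vfit <- vegan::rda(y ~ t + p, data = x)
  expect_equal(fit$total_inertia, unname(vfit$tot.chi), tolerance = 1e-8)
  expect_equal(fit$constrained_inertia, unname(vfit$CCA$tot.chi), tolerance = 1e-8)
  expect_equal(sort(fit$svd$d^2 / (nrow(y) - 1), decreasing = TRUE),
               unname(vfit$CCA$eig), tolerance = 1e-8)
  mine <- predict(fit, as.matrix(x))
  theirs <- predict(vfit, newdata = x, type = "response", model = "CCA")
  expect_equal(unname(mine), unname(as.matrix(theirs)), tolerance = 1e-8)
})

test_that("prediction is exact on calibration data and maps the centroid to the centroid", {
  set.seed(7)
  y <- matrix(rnorm(20), 5, 4)
  x <- matrix(rnorm(10), 5, 2)
  fit <- fit_rda(y, x)
  xc <- sweep(x, 2, fit$x_means)
  expect_equal(predict(fit, x), sweep(xc %*% fit$coefficients, 2, fit$y_means, "+"),
               ignore_attr = TRUE)
  centroid <- matrix(fit$x_means, 1)
  expect_equal(drop(predict(fit, centroid)), fit$y_means, tolerance = 1e-12)
})

test_that("a one-variable model reproduces slope/intercept arithmetic", {
  x <- matrix(c(2, 4, 6), ncol = 1)
  y <- matrix(c(1, 5, 6), ncol = 1)
  fit <- fit_rda(y, x)
  slope <- cov(x, y)[1, 1] / var(x[, 1])
  intercept <- mean(y) - slope * mean(x)
  x_new <- matrix(c(3, 10), ncol = 1)
  expect_equal(drop(predict(fit, x_new)), intercept + slope * c(3, 10),
               tolerance = 1e-12)
})

test_that("rank truncation projects onto leading constrained axes", {
  set.seed(3)
  y <- matrix(rnorm(40), 8, 5)
  x <- matrix(rnorm(24), 8, 3)
  fit <- fit_rda(y, x)
  full <- predict(fit, x)
  expect_equal(predict(fit, x, rank = length(fit$svd$d)), full,
               tolerance = 1e-12, ignore_attr = TRUE)
  r1 <- predict(fit, x, rank = 1)
  # rank-1 fitted matrix has rank 1 after centering
  expect_equal(qr(sweep(r1, 2, fit$y_means))$rank, 1)
})

test_that("rank-deficient constraints fail naming the dependent column", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  y <- matrix(rnorm(8), 4, 2)
  expect_error(fit_rda(y, x), "b", class = "clineshift_rank_error")
})

test_that("with no explanatory columns RDA degenerates to PCA of the response", {
  set.seed(4)
  y <- matrix(rnorm(30), 6, 5)
  fit <- fit_rda(y, matrix(numeric(0), 6, 0))
  pc <- prcomp(y, center = TRUE, scale. = FALSE)
  expect_equal(fit$svd$d^2 / (nrow(y) - 1), unname(pc$sdev^2)[seq_along(fit$svd$d)],
               tolerance = 1e-10)
  expect_equal(abs(fit$svd$v), abs(unname(pc$rotation[, seq_along(fit$svd$d)])),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("saturated indicator constraints reproduce the response exactly", {
  set.seed(9)
  y <- matrix(rpois(24, 15), 6, 4)
  x <- model.matrix(~ factor(1:6))[, -1]
  fit <- fit_rda(y, x)
  expect_equal(predict(fit, x), y, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fit$residual_inertia, 0, tolerance = 1e-10)
})

test_that("CCA with saturated indicators reproduces the counts", {
  set.seed(11)
  y <- matrix(rpois(20, 30) + 1, 5, 4)
  x <- model.matrix(~ factor(1:5))[, -1]
  res <- fit_predict_cca(y, x)
  expect_equal(res$predicted, y, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("CCA fitted counts match an explicit weighted-projection oracle", {
  y <- matrix(c(10, 4, 2, 6,
                3, 9, 5, 2,
                1, 2, 12, 7), 3, 4, byrow = TRUE)
  x <- matrix(c(0.2, 1.4, 2.9), ncol = 1, dimnames = list(NULL, "t"))
  res <- fit_predict_cca(y, x)

  # oracle: direct hat-matrix projection of the chi-square standardized
  # profiles onto the weighted explanatory space
  tot <- sum(y); P <- y / tot
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  Q <- (P - E) / sqrt(E)
  xs <- (x[, 1] - sum(r * x[, 1])) / sqrt(sum(r * (x[, 1] - sum(r * x[, 1]))^2))
  Xw <- cbind(sqrt(r), sqrt(r) * xs)
  H <- Xw %*% solve(t(Xw) %*% Xw) %*% t(Xw)
  pred_oracle <- ((H %*% Q) * sqrt(E) + E) * tot
  expect_equal(res$predicted, pred_oracle, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("CCA extrapolation can go negative and is flagged", {
  y <- matrix(c(30, 2, 10, 12, 2, 30), 3, 2, byrow = TRUE)
  x <- matrix(c(1, 2, 3), ncol = 1)
  expect_warning(res <- fit_predict_cca(y, x, X_new = matrix(c(8, 9, 10), 3, 1)),
                 "negative")
  expect_true(any(res$predicted < 0))
  expect_gt(nrow(res$negative), 0)
})

test_that("AMOVA sums of squares match the pairwise-distance oracle", {
  for (seed in 1:10) {
    ind <- random_individuals(g = 3, ind_per_pop = 4, n_loci = 5, seed = seed)
    res <- amova_rda(ind)
    y <- as.matrix(ind[setdiff(names(ind), c("individual", "population"))])
    oracle <- ss_pairwise(y, ind$population)
    expect_equal(res$table$SS[3], oracle$total, tolerance = 1e-10)
    expect_equal(res$table$SS[2], oracle$within, tolerance = 1e-10)
    expect_equal(res$table$SS[1], oracle$among, tolerance = 1e-10)
    expect_equal(res$table$MS, res$table$SS / res$table$df)
  }
})

test_that("AMOVA df bookkeeping and n0 follow the standard estimators", {
  ind <- random_individuals(g = 4, ind_per_pop = 6, n_loci = 3, seed = 2)
  res <- amova_rda(ind)
  expect_equal(res$table$df, c(3, 20, 23))
  expect_equal(res$n0, (24 - sum(rep(6, 4)^2) / 24) / 3)
})

test_that("AMOVA handles fixation and degenerate inputs", {
  # two maximally differentiated populations, no within variation
  ind <- tibble::tibble(
    individual = paste0("i", 1:6),
    population = rep(c("P1", "P2"), each = 3),
    L1.A = c(2L, 2L, 2L, 0L, 0L, 0L),
    L1.B = c(0L, 0L, 0L, 2L, 2L, 2L))
  res <- amova_rda(ind)
  expect_equal(res$table$SS[2], 0, tolerance = 1e-12)
  expect_equal(res$phi_st, 1)

  same <- ind
  same$L1.A <- 1L; same$L1.B <- 1L
  expect_warning(res2 <- amova_rda(same), "identical")
  expect_equal(res2$table$SS[3], 0, tolerance = 1e-12)
  expect_true(is.na(res2$phi_st))

  one_pop <- ind
  one_pop$population <- "P1"
  expect_error(amova_rda(one_pop), class = "clineshift_validation_error")
})

test_that("AMOVA is invariant to the indicator coding of populations", {
  ind <- random_individuals(g = 3, ind_per_pop = 5, n_loci = 4, seed = 8)
  res1 <- amova_rda(ind)
  flipped <- ind[order(ind$population, decreasing = TRUE), ]
  res2 <- amova_rda(flipped)
  expect_equal(res1$table$SS, res2$table$SS, tolerance = 1e-10)
  expect_equal(res1$phi_st, res2$phi_st, tolerance = 1e-10)
})
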