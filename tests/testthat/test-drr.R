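test_that("ridge variance-component REML dominates a dense grid oracle", {
  set.seed(12)
  n <- 80; q <- 6
  Z <- matrix(sample(c(-1, 1), n * q, replace = TRUE), n)
  y <- drop(Z %*% rnorm(q, 0, 0.5)) + rnorm(n)
  W <- matrix(1, n, 1)
  est <- estimate_ridge_components(y, W, Z)
  grid <- exp(seq(log(1e-6), log(1e6), length.out = 601))
  ll <- vapply(grid, dense_reml_loglik, 0, y = y, W = W, A = tcrossprod(Z))
  expect_gte(dense_reml_loglik(est$lambda, y, W, tcrossprod(Z)) + 1e-6, max(ll))
  step <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(est$lambda) - log(grid[which.max(ll)])), step + 1e-9)
  expect_equal(est$phi2, est$lambda * est$sigma2, tolerance = 1e-12)
})

test_that("ridge REML recovers a known marker-effect variance", {
  phis <- vapply(1:60, function(r) {
    set.seed(400 + r)
    Z <- matrix(sample(c(-1, 1), 1000 * 100, replace = TRUE), 1000)
    y <- drop(Z %*% rnorm(100, 0, 0.2)) + rnorm(1000)
    estimate_ridge_components(y, Z = Z)$phi2
  }, 0)
  expect_gte(median(phis), 0.02)
  expect_lte(median(phis), 0.06)
})

test_that("ridge REML finds little marker variance in pure noise", {
  stats <- vapply(1:60, function(r) {
    set.seed(700 + r)
    Z <- matrix(sample(c(-1, 1), 500 * 50, replace = TRUE), 500)
    y <- rnorm(500)
    est <- suppressWarnings(estimate_ridge_components(y, Z = Z))
    # explained-to-residual variance ratio of the fitted ridge model
    est$lambda * 50 * mean(apply(Z, 2, var))
  }, 0)
  expect_lt(median(stats), 0.1)
})

test_that("ORR BLUP matches the explicit-inverse oracle", {
  set.seed(3)
  n <- 6; q <- 2
  Z <- matrix(c(-1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1), n, q)
  y <- rnorm(n, 0, 2)
  W <- matrix(1, n, 1)
  lambda <- 0.4; sigma2 <- 1.7
  Hi <- solve(lambda * tcrossprod(Z) + diag(n))
  alpha <- drop(solve(t(W) %*% Hi %*% W, t(W) %*% Hi %*% y))
  out <- orr_blup(y, W, Z, alpha, lambda, sigma2)
  gam_o <- lambda * drop(t(Z) %*% Hi %*% (y - W %*% alpha))
  var_o <- sigma2 * diag(lambda * diag(q) -
                         lambda * t(Z) %*% Hi %*% Z * lambda)
  expect_equal(out$gamma_orr, gam_o, tolerance = 1e-10)
  expect_equal(out$var_orr, var_o, tolerance = 1e-10)
  # infinite-shrinkage limit
  z0 <- orr_blup(y, W, Z, alpha, 0, sigma2)
  expect_equal(z0$gamma_orr, c(0, 0))
  expect_equal(z0$var_orr, c(0, 0))
  # posterior variance never exceeds the prior phi^2
  expect_true(all(out$var_orr <= lambda * sigma2 + 1e-12))
})

test_that("the two well-measurement-factor formulas agree", {
  set.seed(14)
  n <- 80; q <- 12
  Z <- matrix(sample(c(-1, 0, 1), n * q, replace = TRUE), n)
  y <- rnorm(n)
  lambda <- 0.3; sigma2 <- 2.1
  W <- matrix(1, n, 1)
  Hi <- solve(lambda * tcrossprod(Z) + diag(n))
  alpha <- drop(solve(t(W) %*% Hi %*% W, t(W) %*% Hi %*% y))
  out <- orr_blup(y, W, Z, alpha, lambda, sigma2)
  phi2 <- lambda * sigma2
  d_from_var <- 1 - out$var_orr / phi2
  d_dense <- lambda * diag(t(Z) %*% Hi %*% Z)
  expect_lt(max(abs(d_from_var - d_dense)), 1e-8)
  expect_lt(max(abs(out$d - d_dense)), 1e-8)
})

test_that("deshrinkage arithmetic and stability floor", {
  ds <- deshrink(0.5, var_orr = 0.05, phi2 = 0.1)
  expect_equal(ds$d, 0.5)
  expect_equal(ds$gamma_drr, 1.0)
  expect_equal(ds$var_drr, 0.1)
  # fully measured effect: DRR equals ORR
  ds1 <- deshrink(0.3, 0, phi2 = 0.2)
  expect_equal(ds1$d, 1)
  expect_equal(ds1$gamma_drr, 0.3)
  # unmeasured marker flagged, not tested
  ds0 <- deshrink(c(0.3, 0.1), c(0.2 * (1 - 1e-12), 0.1), phi2 = 0.2)
  expect_false(ds0$measured[1])
  expect_true(is.na(ds0$gamma_drr[1]))
  expect_true(ds0$measured[2])
  expect_error(deshrink(1, 1, phi2 = 0), "phi2")
  # deshrinking always enlarges magnitudes
  set.seed(4)
  f <- drr_fit(rnorm(60) + rep(c(-1, 1), 30), NULL,
               matrix(sample(c(-1, 1), 60 * 5, TRUE), 60))
  expect_true(all(abs(f$gamma_drr[f$measured]) >=
                  abs(f$gamma_orr[f$measured]) - 1e-12))
})

test_that("single-marker deshrunk estimate equals the OLS slope", {
  # Woodbury identity: with an intercept and a centered marker column,
  # gamma_DRR = OLS slope and var_DRR = sigma^2 / (z'z), for any lambda > 0
  set.seed(15)
  n <- 40
  z <- sample(c(-1, 1), n, replace = TRUE)
  z <- z - mean(z)
  y <- 2 + 0.8 * z + rnorm(n)
  W <- matrix(1, n, 1)
  ols <- coef(lm(y ~ z))[["z"]]
  for (lambda in c(1e-4, 0.1, 5)) {
    sigma2 <- 1.3
    Hi <- solve(lambda * tcrossprod(z) + diag(n))
    alpha <- drop(solve(t(W) %*% Hi %*% W, t(W) %*% Hi %*% y))
    out <- orr_blup(y, W, cbind(z), alpha, lambda, sigma2)
    ds <- deshrink(out$gamma_orr, out$var_orr, lambda * sigma2)
    expect_equal(ds$gamma_drr, ols, tolerance = 1e-8)
    expect_equal(ds$var_drr, sigma2 / sum(z^2), tolerance = 1e-8)
  }
})

test_that("Wald statistics follow chi-square(1) under the null", {
  expect_equal(wald_test(0, 1)$wald, 0)
  expect_equal(wald_test(0, 1)$p_value, 1)
  # distribution-function oracle at the 5% critical value
  p <- pchisq(3.841459, 1, lower.tail = FALSE)
  expect_equal(wald_test(sqrt(3.841459), 1)$p_value, p, tolerance = 1e-12)
  expect_equal(p, 0.05, tolerance = 1e-5)
  # null calibration: 2000 Wald draws from pure-noise fits match chi2(1)
  Wstats <- c()
  for (i in 1:50) {
    set.seed(900 + i)
    Z <- matrix(sample(c(-1, 1), 500 * 40, replace = TRUE), 500)
    f <- suppressWarnings(drr_fit(rnorm(500), NULL, Z))
    Wstats <- c(Wstats, f$wald[f$measured])
  }
  expect_gte(length(Wstats), 1900)
  ks <- suppressWarnings(ks.test(Wstats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(Wstats > 3.841459) - 0.05), 0.02)
})

test_that("Bonferroni calls use the model-marker denominator", {
  calls <- call_significant(c(1e-6, 1e-3), 100)
  expect_equal(calls$threshold, 5e-4)
  expect_identical(calls$detected, 1L)
  expect_identical(call_significant(rep(1, 5), 5)$detected, integer(0))
  expect_identical(call_significant(c(0.1), 0)$detected, integer(0))
})

test_that("Wald statistics are invariant to joint rescaling of y and Z", {
  set.seed(16)
  n <- 120; q <- 8
  Z <- matrix(sample(c(-1, 1), n * q, replace = TRUE), n)
  y <- drop(Z %*% rnorm(q, 0, 0.4)) + rnorm(n)
  f1 <- drr_fit(y, NULL, Z)
  f2 <- drr_fit(3 * y, NULL, 3 * Z)
  expect_equal(f1$wald, f2$wald, tolerance = 1e-6)
})

test_that("degenerate stage-3 inputs are rejected", {
  y <- rnorm(10)
  expect_error(drr_fit(y, NULL, matrix(0, 10, 2)), "zero")
  expect_error(estimate_ridge_components(y, Z = matrix(numeric(0), 10, 0)),
               "q = 0")
  expect_error(drr_fit(y, matrix(1, 10, 2), matrix(rnorm(10), 10, 1)),
               "rank deficient")
})
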