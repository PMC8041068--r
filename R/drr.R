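# Stage 3: multi-locus ridge model on the selected markers.
#
# Model: y = W alpha + Z gamma + eps, gamma_k ~ N(0, phi^2) i.i.d. (a single
# shared marker-effect variance), eps ~ N(0, sigma^2 I).  All quantities are
# computed from a thin SVD Z = U D V', which makes every likelihood
# evaluation and the BLUP/deshrinkage algebra O(n q) after one O(n q^2)
# factorisation, in either the n x n or q x q regime.

svd_econ <- function(Z) {
  s <- svd(Z)
  keep <- s$d > max(dim(Z)) * .Machine$double.eps * max(s$d, 1)
  list(u = s$u[, keep, drop = FALSE], d = s$d[keep],
       v = s$v[, keep, drop = FALSE])
}

#' REML estimation of the ridge variance components
#'
#' Estimates (phi^2, sigma^2) for `y = W alpha + Z gamma + eps` with
#' `gamma_k ~ N(0, phi^2)` by restricted maximum likelihood, profiling over
#' the single ratio `lambda = phi^2 / sigma^2`.  The marginal covariance is
#' `sigma^2 (lambda Z Z' + I)`; a thin SVD of Z reduces each evaluation to
#' O(n q), and lambda is optimised on the log scale (grid bracket + Brent).
#' `alpha` is the generalized-least-squares estimate at the optimum.
#'
#' @param y phenotype vector.
#' @param W fixed-effect design (default intercept); full column rank.
#' @param Z n x q matrix of selected markers, q >= 1.
#' @param bounds search interval for lambda.
#' @return list with `phi2`, `sigma2`, `lambda`, `alpha_hat`, `loglik`,
#'   `boundary`.
#' @export
estimate_ridge_components <- function(y, W = NULL, Z, bounds = c(1e-6, 1e6)) {
  Z <- as.matrix(Z)
  n <- length(y)
  if (ncol(Z) < 1) stop("no markers in the model (q = 0)", call. = FALSE)
  if (nrow(Z) != n) stop("nrow(Z) must equal length(y)", call. = FALSE)
  if (all(Z == 0)) stop("Z is identically zero", call. = FALSE)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  if (qr(W)$rank < ncol(W))
    stop("fixed-effect design W is rank deficient", call. = FALSE)
  sv <- svd_econ(Z)
  est <- .ridge_reml_svd(y, W, sv, n, bounds)
  list(phi2 = est$lambda * est$sigma2, sigma2 = est$sigma2,
       lambda = est$lambda, alpha_hat = est$alpha, loglik = est$loglik,
       boundary = est$boundary)
}

.ridge_reml_svd <- function(y, W, sv, n, bounds = c(1e-6, 1e6)) {
  # eigenbasis of ZZ': eigenvalues d^2 on span(U), 0 on the complement.
  ytil <- drop(crossprod(sv$u, y))
  Wtil <- crossprod(sv$u, W)
  extra_yy <- sum(y^2) - sum(ytil^2)
  extra_Wy <- crossprod(W, y) - crossprod(Wtil, ytil)
  extra_WW <- crossprod(W) - crossprod(Wtil)
  reml_optimize(ytil, Wtil, sv$d^2, extra_yy, extra_Wy, extra_WW,
                n = n, bounds = bounds)
}

#' Ridge-regression BLUP of marker effects
#'
#' Computes the ordinary ridge regression (ORR) estimates: the best linear
#' unbiased prediction `gamma_ORR = lambda Z' H^-1 (y - W alpha)` with
#' `H = lambda Z Z' + I`, and the conditional (posterior) variances
#' `var(gamma_ORR_k | y) = phi^2 (1 - d_k)` where
#' `d_k = lambda Z_k' H^-1 Z_k`.  Variances are returned in absolute
#' (phenotype^2) units, i.e. multiplied by sigma^2.
#'
#' @param y phenotype vector.
#' @param W fixed-effect design (default intercept).
#' @param Z n x q selected marker matrix.
#' @param alpha_hat fixed-effect estimates (e.g. from
#'   [estimate_ridge_components()]).
#' @param lambda variance ratio phi^2 / sigma^2 (>= 0).
#' @param sigma2 residual variance used to scale the variances.
#' @return list with per-marker `gamma_orr`, `var_orr`, and the
#'   well-measurement factors `d`.
#' @export
orr_blup <- function(y, W = NULL, Z, alpha_hat, lambda, sigma2 = 1) {
  Z <- as.matrix(Z)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (lambda == 0) {
    q <- ncol(Z)
    return(list(gamma_orr = numeric(q), var_orr = numeric(q), d = numeric(q)))
  }
  sv <- svd_econ(Z)
  .orr_from_svd(y, as.matrix(W), Z, sv, alpha_hat, lambda, sigma2)
}

.orr_from_svd <- function(y, W, Z, sv, alpha_hat, lambda, sigma2) {
  r <- y - drop(W %*% alpha_hat)
  g <- lambda * sv$d^2 / (1 + lambda * sv$d^2)
  # H^-1 r = r - U diag(g) U' r
  Hinv_r <- r - drop(sv$u %*% (g * drop(crossprod(sv$u, r))))
  gamma_orr <- lambda * drop(crossprod(Z, Hinv_r))
  # diag(Z' H^-1 Z) = rowSums(V^2 scaled by d^2 / (1 + lambda d^2))
  d <- lambda * drop(sv$v^2 %*% (sv$d^2 / (1 + lambda * sv$d^2)))
  d <- pmin(pmax(d, 0), 1)
  phi2 <- lambda * sigma2
  var_orr <- phi2 * (1 - d)
  list(gamma_orr = gamma_orr, var_orr = var_orr, d = d)
}

#' Deshrink ridge estimates by the well-measurement factor
#'
#' The well-measurement factor `d_k = 1 - var(gamma_ORR_k|y) / phi^2` (the
#' effective degree of freedom of marker k) rescales the shrunken ridge
#' estimates back to unbiased-scale effects:
#' `gamma_DRR_k = gamma_ORR_k / d_k`, `var(gamma_DRR_k) = var_orr_k / d_k`.
#' Markers with `d_k` at or below the stability floor are flagged as
#' unmeasured (`NA` estimates) and excluded from testing.
#'
#' @param gamma_orr,var_orr per-marker ridge estimates and conditional
#'   variances (absolute units) from [orr_blup()].
#' @param phi2 prior marker-effect variance (> 0).
#' @param floor stability floor for d_k (default 1e-8).
#' @return list with `d`, `gamma_drr`, `var_drr`, and logical `measured`.
#' @export
deshrink <- function(gamma_orr, var_orr, phi2, floor = 1e-8) {
  if (phi2 <= 0) stop("phi2 must be > 0 to deshrink", call. = FALSE)
  d <- 1 - var_orr / phi2
  measured <- d > floor
  gamma_drr <- ifelse(measured, gamma_orr / d, NA_real_)
  var_drr <- ifelse(measured, var_orr / d, NA_real_)
  list(d = d, gamma_drr = gamma_drr, var_drr = var_drr, measured = measured)
}

#' Wald chi-square tests of deshrunk effects
#'
#' `W_k = gamma_DRR_k^2 / var(gamma_DRR_k)`, referred to a chi-square
#' distribution with one degree of freedom under H0: gamma_k = 0.
#'
#' @param gamma_drr,var_drr deshrunk effects and variances (NA entries are
#'   propagated with p = NA).
#' @return list with `wald` statistics and `p_value`s.
#' @export
wald_test <- function(gamma_drr, var_drr) {
  wald <- gamma_drr^2 / var_drr
  p <- pchisq(wald, df = 1, lower.tail = FALSE)
  list(wald = wald, p_value = p)
}

#' Bonferroni significance calls
#'
#' Declares markers significant when `p < alpha / n_model_markers`, where the
#' denominator is the number of markers in the fitted multi-locus model.
#'
#' @param p_values per-marker p-values (NA never significant).
#' @param n_model_markers Bonferroni denominator.
#' @param alpha family-wise level (default 0.05).
#' @return list with integer `detected` indices and the `threshold` used.
#' @export
call_significant <- function(p_values, n_model_markers, alpha = 0.05) {
  if (n_model_markers < 1) return(list(detected = integer(), threshold = NA_real_))
  thr <- alpha / n_model_markers
  list(detected = which(!is.na(p_values) & p_values < thr), threshold = thr)
}

#' Fit the deshrinking ridge regression on a set of selected markers
#'
#' Convenience wrapper running [estimate_ridge_components()], [orr_blup()],
#' [deshrink()] and [wald_test()] with one shared SVD of Z.
#'
#' @inheritParams estimate_ridge_components
#' @param dk_floor stability floor for the well-measurement factor.
#' @return A `drr_fit` object: per-marker vectors `gamma_orr`, `var_orr`,
#'   `d`, `gamma_drr`, `var_drr`, `wald`, `p_value`, `measured`, plus `phi2`,
#'   `sigma2`, `lambda`, `alpha_hat`, `loglik`, `boundary`.
#' @export
drr_fit <- function(y, W = NULL, Z, bounds = c(1e-6, 1e6), dk_floor = 1e-8) {
  Z <- as.matrix(Z)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  if (ncol(Z) < 1) stop("no markers in the model (q = 0)", call. = FALSE)
  if (all(Z == 0)) stop("Z is identically zero", call. = FALSE)
  if (qr(W)$rank < ncol(W))
    stop("fixed-effect design W is rank deficient", call. = FALSE)
  sv <- svd_econ(Z)
  est <- .ridge_reml_svd(y, W, sv, n, bounds)
  orr <- .orr_from_svd(y, W, Z, sv, est$alpha, est$lambda, est$sigma2)
  phi2 <- est$lambda * est$sigma2
  ds <- deshrink(orr$gamma_orr, orr$var_orr, phi2, dk_floor)
  wt <- wald_test(ds$gamma_drr, ds$var_drr)
  structure(list(gamma_orr = orr$gamma_orr, var_orr = orr$var_orr,
                 d = ds$d, gamma_drr = ds$gamma_drr, var_drr = ds$var_drr,
                 measured = ds$measured, wald = wt$wald, p_value = wt$p_value,
                 phi2 = phi2, sigma2 = est$sigma2, lambda = est$lambda,
                 alpha_hat = est$alpha, loglik = est$loglik,
                 boundary = est$boundary, q = ncol(Z)),
            class = "drr_fit")
}

# Genome-prior stage 3 (pipeline default): every panel marker is a random
# effect, so the ridge covariance phi^2 Z_all Z_all' + sigma^2 I coincides
# (after absorbing column means into the intercept) with sigma^2 B,
# B = lambda_g K + I.  The variance components are inherited from the
# stage-1 REML fit: phi^2 = sigma_g^2 / s0 with s0 = mean diag of Xc Xc',
# and H = B, so all quantities reuse the kinship eigendecomposition.
# In this regime d_k is small and gamma_DRR_k reduces to the marginal GLS
# estimator Zc_k' B^-1 (y - W alpha) / (Zc_k' B^-1 Zc_k).
.drr_genome_fit <- function(y, W, Zsel, eig, lambda_g, est, s0, dk_floor) {
  q <- ncol(Zsel)
  delta <- pmax(eig$values, 0)
  wts <- 1 / (lambda_g * delta + 1)
  alpha <- est$alpha
  sigma2 <- est$sigma2
  r <- y - drop(W %*% alpha)
  Zc <- sweep(Zsel, 2, colMeans(Zsel))
  Tm <- crossprod(eig$vectors, Zc)
  Binv_r <- drop(eig$vectors %*% (wts * drop(crossprod(eig$vectors, r))))
  lam <- lambda_g / s0                       # phi^2 / sigma^2
  gamma_orr <- lam * drop(crossprod(Zc, Binv_r))
  d <- lam * drop(crossprod(Tm^2, wts))      # lam * diag(Zc' B^-1 Zc)
  d <- pmin(pmax(d, 0), 1)
  phi2 <- lam * sigma2
  var_orr <- phi2 * (1 - d)
  if (phi2 > 0) {
    ds <- deshrink(gamma_orr, var_orr, phi2, dk_floor)
  } else {
    ds <- list(d = d, gamma_drr = rep(NA_real_, q),
               var_drr = rep(NA_real_, q), measured = rep(FALSE, q))
  }
  wt <- wald_test(ds$gamma_drr, ds$var_drr)
  structure(list(gamma_orr = gamma_orr, var_orr = var_orr,
                 d = ds$d, gamma_drr = ds$gamma_drr, var_drr = ds$var_drr,
                 measured = ds$measured, wald = wt$wald, p_value = wt$p_value,
                 phi2 = phi2, sigma2 = sigma2, lambda = lam,
                 alpha_hat = alpha, loglik = est$loglik,
                 boundary = est$boundary, q = q),
            class = "drr_fit")
}

#' @export
print.drr_fit <- function(x, ...) {
  cat(sprintf(
    "drr_fit: q = %d markers, phi2 = %.4g, sigma2 = %.4g, lambda = %.4g\n",
    x$q, x$phi2, x$sigma2, x$lambda))
  cat(sprintf("  %d measured (d_k above floor), min Wald p = %.3g\n",
              sum(x$measured), suppressWarnings(min(x$p_value, na.rm = TRUE))))
  invisible(x)
}
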