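#' Marker-derived relatedness matrix
#'
#' Computes the genomic relationship matrix `K = Xc Xc' / s` from the
#' column-centered genotype matrix `Xc`, with the scalar `s` chosen so that
#' `mean(diag(K)) = 1`.  K is symmetric positive semi-definite by
#' construction; on this scale the polygenic-to-residual variance ratio
#' lambda_g is directly comparable with the simulation multiplier c.
#'
#' @param geno a `genotype_matrix` or plain n x m numeric matrix.
#' @return n x n relatedness matrix with sample dimnames.
#' @export
compute_kinship <- function(geno) {
  X <- geno_matrix(geno)
  if (nrow(X) < 2)
    stop("need at least 2 samples", call. = FALSE)
  # centered cross-product via the rank-1 identity
  # Xc Xc' = X X' - a 1' - 1 a' + (mu'mu) 1 1',  a = X mu,
  # avoiding a centered copy of X
  mu <- colMeans(X)
  K <- tcrossprod(X)
  a <- drop(X %*% mu)
  K <- K - outer(a, rep(1, nrow(X))) - outer(rep(1, nrow(X)), a) +
    sum(mu^2)
  s <- mean(diag(K))
  if (s <= 0)
    stop("all markers are monomorphic; kinship undefined", call. = FALSE)
  K / s
}

# Profile restricted log-likelihood of lambda for y = W alpha + e,
# Var(e) = sigma^2 (lambda * A + I), evaluated in a (possibly partial)
# eigenbasis of A.
#
# ytil, Wtil: rotated y and W for the eigenvectors with eigenvalue in
# `delta`; `extra_yy`, `extra_Wy`, `extra_WW` carry the contributions of the
# orthogonal complement (where A acts as 0), so that the full quadratic forms
# are e.g. y' Sigma^-1 y = sum(ytil^2 / w) + extra_yy with w = lambda*delta+1.
# Returns the criterion and the implied sigma^2 / alpha.
reml_profile <- function(lambda, ytil, Wtil, delta,
                         extra_yy = 0, extra_Wy = 0, extra_WW = 0,
                         n = length(ytil) , want_alpha = FALSE) {
  w <- lambda * delta + 1
  c_ <- ncol(Wtil)
  iw <- 1 / w
  yy <- sum(ytil^2 * iw) + extra_yy
  Wy <- crossprod(Wtil, ytil * iw) + extra_Wy
  WW <- crossprod(Wtil, Wtil * iw) + extra_WW
  ch <- tryCatch(chol(WW), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  alpha <- backsolve(ch, forwardsolve(t(ch), Wy))
  rss <- max(yy - sum(Wy * alpha), 1e-300)
  nc <- n - c_
  sigma2 <- rss / nc
  # log|Sigma| over the delta-part only; the complement contributes 0
  loglik <- -0.5 * (nc * (log(2 * pi * sigma2) + 1) +
                    sum(log(w)) + 2 * sum(log(diag(ch))))
  list(loglik = loglik, sigma2 = sigma2, alpha = drop(alpha), rss = rss)
}

# 1-D REML optimisation over lambda on the log scale: coarse log-spaced grid
# to bracket, then Brent refinement via optimize().
reml_optimize <- function(ytil, Wtil, delta,
                          extra_yy = 0, extra_Wy = 0, extra_WW = 0,
                          n = length(ytil),
                          bounds = c(1e-6, 1e6), grid_n = 25L) {
  f <- function(loglam)
    reml_profile(exp(loglam), ytil, Wtil, delta,
                 extra_yy, extra_Wy, extra_WW, n)$loglik
  lo <- log(bounds[1]); hi <- log(bounds[2])
  grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(grid, f, 0)
  i <- which.max(ll)
  bracket <- c(grid[max(1, i - 1)], grid[min(grid_n, i + 1)])
  opt <- optimize(f, bracket, maximum = TRUE, tol = 1e-8)
  # accept the better of grid argmax and refined optimum
  if (opt$objective >= ll[i]) {
    loglam <- opt$maximum; best <- opt$objective
  } else {
    loglam <- grid[i]; best <- ll[i]
  }
  boundary <- loglam <= lo + 1e-6 || loglam >= hi - 1e-6
  lambda <- exp(loglam)
  # snap the boundary estimate at the lower bound to an effective zero
  fit <- reml_profile(lambda, ytil, Wtil, delta,
                      extra_yy, extra_Wy, extra_WW, n, want_alpha = TRUE)
  list(lambda = lambda, loglik = best, sigma2 = fit$sigma2,
       alpha = fit$alpha, boundary = boundary)
}

#' REML estimate of the polygenic-to-residual variance ratio
#'
#' Fits the reduced polygenic model `y = W alpha + u + eps` with
#' `u ~ MVN(0, sigma_g^2 K)`, `eps ~ N(0, sigma^2 I)` by restricted maximum
#' likelihood, profiling everything but lambda_g = sigma_g^2 / sigma^2.  One
#' eigendecomposition of K reduces each likelihood evaluation to O(n), and
#' lambda_g is optimised on the log scale (coarse grid bracket + Brent).
#'
#' @param y numeric phenotype vector.
#' @param W fixed-effect design matrix (default: intercept only); must have
#'   full column rank.
#' @param K n x n symmetric PSD relatedness matrix.
#' @param bounds search interval for lambda_g (default `c(1e-6, 1e6)`).
#' @return A `variance_ratios` object: `lambda_g`, `lambda_gamma` (fixed at 0
#'   during screening), `sigma2`, `log_restricted_likelihood`, `alpha`, and a
#'   `boundary` flag set when the optimum sits at a search bound.
#' @export
estimate_lambda_g <- function(y, W = NULL, K, bounds = c(1e-6, 1e6)) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  if (qr(W)$rank < ncol(W))
    stop("fixed-effect design W is rank deficient", call. = FALSE)
  if (n <= ncol(W))
    stop("need more observations than fixed effects", call. = FALSE)
  eig <- eigen(K, symmetric = TRUE)
  est <- .reml_lambda_eig(y, W, eig, bounds)
  structure(list(lambda_g = est$lambda, lambda_gamma = 0,
                 sigma2 = est$sigma2,
                 log_restricted_likelihood = est$loglik,
                 alpha = est$alpha, boundary = est$boundary),
            class = "variance_ratios")
}

# shared with run_fastrr(), which reuses a single eigendecomposition of K
.reml_lambda_eig <- function(y, W, eig, bounds = c(1e-6, 1e6)) {
  delta <- pmax(eig$values, 0)
  ytil <- drop(crossprod(eig$vectors, y))
  Wtil <- crossprod(eig$vectors, W)
  est <- reml_optimize(ytil, Wtil, delta, n = length(y), bounds = bounds)
  if (est$boundary && est$lambda <= bounds[1] * exp(1e-6)) {
    warning("lambda_g optimum at the lower search bound; treating as ~0",
            call. = FALSE)
  } else if (est$boundary) {
    warning("lambda_g optimum at the upper search bound", call. = FALSE)
  }
  est
}

#' @export
print.variance_ratios <- function(x, ...) {
  cat(sprintf(
    "variance_ratios: lambda_g = %.4g, sigma2 = %.4g, logREML = %.3f%s\n",
    x$lambda_g, x$sigma2, x$log_restricted_likelihood,
    if (isTRUE(x$boundary)) " (boundary)" else ""))
  invisible(x)
}
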