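# Shared fixtures built in code.

# small random two-class genotype matrix with dimnames
toy_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  X <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
  dimnames(X) <- list(sprintf("S%04d", seq_len(n)), sprintf("M%05d", seq_len(m)))
  X
}

# random PSD relatedness matrix scaled to mean diagonal 1
toy_kinship <- function(n, seed = 1) {
  compute_kinship(toy_geno(n, 3 * n, seed))
}

# dense-algebra restricted log-likelihood oracle for
# y = W a + e, Var(e) = sigma^2 (lambda * A + I): explicit solve()/determinant
# route, independent of the package's eigen-based profile.
dense_reml_loglik <- function(lambda, y, W, A) {
  n <- length(y)
  c_ <- ncol(W)
  Sigma <- lambda * A + diag(n)
  Si <- solve(Sigma)
  WW <- t(W) %*% Si %*% W
  alpha <- solve(WW, t(W) %*% Si %*% y)
  r <- y - W %*% alpha
  rss <- drop(t(r) %*% Si %*% r)
  sigma2 <- rss / (n - c_)
  -0.5 * ((n - c_) * (log(2 * pi * sigma2) + 1) +
          determinant(Sigma)$modulus + determinant(WW)$modulus)
}

# craft a screen_result with prescribed p-values (for selection-rule tests)
fake_scan <- function(p, threshold = 0.01) {
  fastrr:::`.scan_result`(r = sqrt(1 - p), n = 100, threshold = threshold,
                          markers = sprintf("M%05d", seq_along(p))) -> res
  res$p <- p
  res$selected <- res$p < threshold
  res
}
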