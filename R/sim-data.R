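#' Generate a synthetic genotype matrix
#'
#' Draws one minor allele frequency per marker from
#' Uniform(maf_low, maf_high), then samples independent genotypes.  Under
#' `two_class` coding (inbred panel) each entry is -1 with probability MAF and
#' +1 with probability 1 - MAF.  Under `hwe_three_class` coding the genotypes
#' -1 / 0 / +1 occur with Hardy-Weinberg frequencies q^2, 2q(1-q), (1-q)^2.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; identical (config, seed) pairs regenerate
#'   bit-identical matrices.
#' @return A `genotype_matrix`: list with `X` (n x m numeric matrix with
#'   sample/marker dimnames), `maf` (drawn per-marker MAFs), `positions`
#'   (1-based indices) and `coding`.
#' @export
generate_genotypes <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_markers
  set.seed(as.integer(seed))
  maf <- runif(m, config$maf_low, config$maf_high)
  u <- runif(n * m)
  pm <- rep(maf, each = n)
  if (config$genotype_coding == "two_class") {
    X <- 1 - 2 * (u < pm)
  } else {
    # cumulative HWE bins: [0,q^2) -> -1, [q^2, q^2+2q(1-q)) -> 0, else +1
    X <- (u >= pm^2) + (u >= pm * (2 - pm)) - 1
  }
  dim(X) <- c(n, m)
  dimnames(X) <- list(sprintf("S%04d", seq_len(n)), sprintf("M%05d", seq_len(m)))
  structure(list(X = X, maf = maf, positions = seq_len(m),
                 coding = config$genotype_coding),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%s coding)\n",
              nrow(x$X), ncol(x$X), x$coding))
  cat(sprintf("  MAF range [%.3f, %.3f]\n", min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$X

#' @export
dim.genotype_matrix <- function(x) dim(x$X)

# Accept either a genotype_matrix or a plain numeric matrix.
geno_matrix <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno$X
  else if (is.matrix(geno)) geno
  else stop("expected a genotype_matrix or a numeric matrix", call. = FALSE)
}

#' Simulate a phenotype from the additive polygenic model
#'
#' Draws `y = mu * 1 + sum_k Z_k gamma_k + u + eps` with polygenic values
#' `u ~ MVN(0, sigma_g^2 * K)` and residuals `eps ~ N(0, sigma^2 I)`, where
#' mu, sigma^2, the polygenic variance sigma_g^2 and the QTN layout come from
#' `config`.  With K scaled to mean diagonal 1 (see [compute_kinship()]),
#' `polygenic_variance = c` reproduces the c-times-K background scenarios
#' (covariance c * K).
#'
#' @param geno a `genotype_matrix` (or plain n x m matrix).
#' @param K n x n symmetric positive semi-definite relatedness matrix; a tiny
#'   diagonal jitter is added before the Cholesky factorisation.
#' @param config a [sim_config()].
#' @param seed integer seed for the random draws.
#' @return list with `y` (named phenotype vector) and `truth`, a `sim_truth`
#'   record of QTN positions/effects, realized MAFs at the QTNs, the polygenic
#'   vector `u`, and the seed.
#' @export
generate_phenotype <- function(geno, K, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  X <- geno_matrix(geno)
  n <- nrow(X)
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
    stop("K must be an n x n matrix matching the genotypes", call. = FALSE)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("K must be symmetric", call. = FALSE)
  set.seed(as.integer(seed))
  sigma2 <- config$residual_variance
  cmult <- config$polygenic_variance
  u <- numeric(n)
  if (cmult > 0) {
    R <- tryCatch(chol(K + diag(1e-8 * mean(diag(K)) + 1e-12, n)),
                  error = function(e)
                    stop("Cholesky factorisation of K failed; K is not ",
                         "positive semi-definite: ", conditionMessage(e),
                         call. = FALSE))
    u <- sqrt(cmult) * drop(crossprod(R, rnorm(n)))
  }
  g <- numeric(n)
  if (length(config$qtn_positions))
    g <- drop(X[, config$qtn_positions, drop = FALSE] %*% config$qtn_effects)
  eps <- if (sigma2 > 0) rnorm(n, 0, sqrt(sigma2)) else numeric(n)
  y <- config$grand_mean + g + u + eps
  names(y) <- rownames(X)
  maf_realized <- if (length(config$qtn_positions))
    colMeans(X[, config$qtn_positions, drop = FALSE] == -1) else numeric()
  truth <- structure(list(qtn_positions = config$qtn_positions,
                          qtn_effects = config$qtn_effects,
                          qtn_maf = maf_realized,
                          u = u, seed = as.integer(seed)),
                     class = "sim_truth")
  list(y = y, truth = truth)
}

#' Draw a random QTN design with a fixed joint variance contribution
#'
#' Samples `n_qtn` distinct marker positions and assigns effects so that the
#' realized joint contribution of the QTNs to the phenotypic variance equals
#' `total_h2`: the QTN variance budget is `V = total_h2 * sigma2 /
#' (1 - total_h2)`, split across QTNs by `shares`, and each effect is
#' `gamma_k = sign_k * sqrt(share_k * V / var(Z_k))` on the realized genotype
#' variances, with random signs.
#'
#' @param n_qtn number of QTNs (<= number of markers).
#' @param total_h2 joint QTN fraction of phenotypic variance, in (0, 1).
#' @param geno a `genotype_matrix` (or matrix) supplying realized variances.
#' @param seed integer seed.
#' @param residual_variance sigma^2 used in the variance budget (default 10,
#'   matching the standard scenarios).
#' @param shares per-QTN variance shares (recycled/normalised to sum 1);
#'   default equal shares.
#' @return list with integer `positions` and numeric `effects`.
#' @export
random_qtn_design <- function(n_qtn, total_h2, geno, seed,
                              residual_variance = 10, shares = NULL) {
  X <- geno_matrix(geno)
  m <- ncol(X)
  if (n_qtn < 1 || n_qtn > m)
    stop("n_qtn must be in 1..n_markers", call. = FALSE)
  if (!(total_h2 > 0 && total_h2 < 1))
    stop("total_h2 must lie strictly in (0, 1)", call. = FALSE)
  if (is.null(shares)) shares <- rep(1 / n_qtn, n_qtn)
  if (length(shares) != n_qtn || any(shares < 0) || sum(shares) <= 0)
    stop("shares must be n_qtn non-negative values", call. = FALSE)
  shares <- shares / sum(shares)
  set.seed(as.integer(seed))
  positions <- sort(sample.int(m, n_qtn))
  v <- apply(X[, positions, drop = FALSE], 2, var)
  if (any(v == 0))
    stop("sampled a monomorphic marker; cannot place a QTN on it", call. = FALSE)
  V_budget <- total_h2 * residual_variance / (1 - total_h2)
  effects <- sqrt(shares * V_budget / v) * sample(c(-1, 1), n_qtn, TRUE)
  list(positions = positions, effects = effects)
}

#' One-call scenario simulation
#'
#' Generates genotypes, the marker-derived kinship, and a phenotype for one
#' replicate of a scenario.  For `random-qtn` presets the QTN layout is drawn
#' first (seed offset 2e7) and written into the returned config.
#'
#' @param config a [sim_config()].
#' @param seed replicate seed; genotypes use `seed`, the phenotype draws use
#'   `seed + 1e7` so the two streams do not overlap.
#' @return list with `geno`, `K`, `y`, `truth`, `config` (possibly with the
#'   drawn QTN layout filled in).
#' @export
simulate_dataset <- function(config, seed) {
  seed <- as.integer(seed)
  geno <- generate_genotypes(config, seed)
  rq <- attr(config, "random_qtn")
  if (!is.null(rq)) {
    des <- random_qtn_design(rq$n_qtn, rq$total_h2, geno, seed + 2e7L,
                             residual_variance = config$residual_variance)
    config$qtn_positions <- des$positions
    config$qtn_effects <- des$effects
  }
  K <- compute_kinship(geno)
  ph <- generate_phenotype(geno, K, config, seed + 1e7L)
  list(geno = geno, K = K, y = ph$y, truth = ph$truth, config = config)
}
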