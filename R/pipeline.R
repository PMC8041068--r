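#' Pipeline configuration
#'
#' @param screen_threshold p-value cutoff of the marginal-correlation screen
#'   (strict `<`), default 0.01.
#' @param alpha family-wise significance level for the Wald calls,
#'   default 0.05.
#' @param bonferroni Bonferroni denominator: `"model_markers"` (the q markers
#'   in the fitted multi-locus model; default) or `"all_markers"` (genome-wide
#'   m).
#' @param ridge_prior scope of the random-effect prior in stage 3.
#'   `"genome"` (default): every marker of the panel is a random effect, so
#'   the ridge covariance is the genomic covariance `phi^2 Z_all Z_all' +
#'   sigma^2 I`; the variance components are inherited from stage 1
#'   (`phi^2 = sigma_g^2 / s0`, with `s0` the kinship scaling), H equals the
#'   whitening matrix B, and the deshrunk estimate is the marginal
#'   generalized-least-squares estimator of each selected marker.  `"model"`:
#'   only the q selected markers carry the prior; (phi^2, sigma^2) are
#'   re-estimated by REML on the selected design via
#'   [estimate_ridge_components()].
#' @param drr_on_whitened if TRUE and `ridge_prior = "model"`, stage 3 runs
#'   on the whitened phenotype and markers instead of the untransformed data
#'   (sensitivity analysis).
#' @param dk_floor stability floor for the well-measurement factor d_k.
#' @param lambda_bounds search interval for both variance-ratio
#'   optimisations.
#' @param workers reserved worker count for block-parallel screening; results
#'   are deterministic and independent of its value.
#' @return A `fastrr_config` list.
#' @export
fastrr_config <- function(screen_threshold = 0.01,
                          alpha = 0.05,
                          bonferroni = c("model_markers", "all_markers"),
                          ridge_prior = c("genome", "model"),
                          drr_on_whitened = FALSE,
                          dk_floor = 1e-8,
                          lambda_bounds = c(1e-6, 1e6),
                          workers = 1L) {
  stopifnot(screen_threshold > 0, screen_threshold < 1,
            alpha > 0, alpha < 1, workers >= 1)
  structure(list(screen_threshold = screen_threshold, alpha = alpha,
                 bonferroni = match.arg(bonferroni),
                 ridge_prior = match.arg(ridge_prior),
                 drr_on_whitened = drr_on_whitened,
                 dk_floor = dk_floor, lambda_bounds = lambda_bounds,
                 workers = as.integer(workers)),
            class = "fastrr_config")
}

# Marginal scan evaluated in the eigenbasis of K, avoiding materialising the
# whitener C and the whitened marker matrix: with Z_c = Q S Q'Z and
# S = diag((lambda_g * delta + 1)^-1/2), all Pearson moments reduce to
# column sums over T = Q'Z.  Numerically identical to
# marginal_scan(whiten(...)$y_c, whiten(...)$Z_c).
.fast_scan <- function(Q, delta, lambda_g, y, Z, threshold) {
  n <- length(y)
  s2 <- 1 / (lambda_g * pmax(delta, 0) + 1)
  Tm <- crossprod(Q, Z)                      # n x m rotation (the only dgemm)
  ytil <- drop(crossprod(Q, y))
  q1 <- drop(crossprod(Q, rep(1, n)))
  ssq_y <- sum(s2 * ytil^2)
  mu_y <- sum(s2 * q1 * ytil) / n
  css_y <- ssq_y - n * mu_y^2
  dot <- drop(crossprod(Tm, s2 * ytil))       # y_c' Z_c per column
  mu_z <- drop(crossprod(Tm, s2 * q1)) / n
  ssq_z <- drop(crossprod(Tm^2, s2))
  css_z <- ssq_z - n * mu_z^2
  ok <- css_z > .Machine$double.eps * n * pmax(1, ssq_z / n)
  r <- rep(NA_real_, ncol(Z))
  num <- dot - n * mu_y * mu_z
  r[ok] <- num[ok] / sqrt(css_z[ok] * css_y)
  r[ok] <- pmin(1, pmax(-1, r[ok]))
  .scan_result(r, n, threshold,
               markers = colnames(Z) %||% sprintf("M%05d", seq_len(ncol(Z))))
}

#' Run the FastRR pipeline
#'
#' Executes the three stages end-to-end: marker-derived kinship (or a
#' supplied matrix) -> REML estimate of lambda_g -> whitening -> marginal
#' correlation screen (p < `screen_threshold`) -> deshrinking ridge
#' regression on the selected markers (on the untransformed data, unless
#' `drr_on_whitened`) -> Wald chi-square tests with Bonferroni calls.
#'
#' Sample alignment: when both genotype rows and the phenotype are named, the
#' analysis uses the (inner-join) intersection and reports the number of
#' dropped samples; otherwise rows are assumed aligned.
#'
#' @param geno a `genotype_matrix` or plain n x m numeric matrix.
#' @param phenotype numeric vector (optionally named by sample).
#' @param covariates optional numeric matrix/data.frame of fixed-effect
#'   covariates; an intercept is always included.
#' @param config a [fastrr_config()].
#' @param kinship optional precomputed n x n relatedness matrix; by default
#'   computed from all markers with [compute_kinship()].
#' @param verbose print one log line per stage.
#' @return A `fastrr_result` data frame, one row per marker tested in stage 3
#'   (zero rows when the screen selects nothing), with columns `marker`,
#'   `index`, `r`, `p_screen`, `gamma_orr`, `gamma_drr`, `se_drr`, `d`,
#'   `wald`, `p_value`, `significant`.  Attributes carry `lambda_g`,
#'   `sigma2`, `q`, `n`, `m`, `threshold` (Bonferroni cutoff), `phi2`,
#'   `dropped_samples`, and the `config`.
#' @export
run_fastrr <- function(geno, phenotype, covariates = NULL,
                       config = fastrr_config(), kinship = NULL,
                       verbose = FALSE) {
  X <- geno_matrix(geno)
  y <- phenotype
  dropped <- 0L
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    ids <- intersect(rownames(X), names(y))
    if (length(ids) == 0)
      stop("no overlapping sample IDs between genotypes and phenotype",
           call. = FALSE)
    dropped <- (nrow(X) - length(ids)) + (length(y) - length(ids))
    if (dropped > 0 && verbose)
      message("dropped ", dropped, " non-overlapping samples")
    X <- X[ids, , drop = FALSE]
    y <- y[ids]
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)
      if (!is.null(rownames(covariates))) covariates <- covariates[ids, , drop = FALSE]
    }
  } else {
    if (length(y) != nrow(X))
      stop("phenotype length does not match genotype rows", call. = FALSE)
  }
  n <- nrow(X); m <- ncol(X)
  if (sd(y) == 0) stop("phenotype is constant", call. = FALSE)
  colvar <- colSums(X^2) / n - colMeans(X)^2
  if (all(colvar <= 0))
    stop("no polymorphic markers", call. = FALSE)
  W <- matrix(1, n, 1)
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  if (qr(W)$rank < ncol(W))
    stop("fixed-effect design (intercept + covariates) is rank deficient",
         call. = FALSE)

  # stage 1: kinship, lambda_g REML, whitening (shared eigendecomposition)
  K <- if (is.null(kinship)) compute_kinship(X) else as.matrix(kinship)
  if (nrow(K) != n || ncol(K) != n)
    stop("kinship dimensions do not match the genotypes", call. = FALSE)
  eig <- eigen(K, symmetric = TRUE)
  est <- .reml_lambda_eig(y, W, eig, config$lambda_bounds)
  lambda_g <- est$lambda
  if (verbose)
    message(sprintf("stage 1: lambda_g = %.4g (sigma2 = %.4g)",
                    lambda_g, est$sigma2))

  # stage 2: marginal correlation screen on whitened data
  scan <- .fast_scan(eig$vectors, eig$values, lambda_g, y, X,
                     config$screen_threshold)
  sel <- select_candidates(scan, config$screen_threshold)
  q <- length(sel)
  if (verbose)
    message(sprintf("stage 2: %d of %d markers selected (p < %g)",
                    q, m, config$screen_threshold))

  empty <- function() {
    res <- data.frame(marker = character(), index = integer(), r = numeric(),
                      p_screen = numeric(), gamma_orr = numeric(),
                      gamma_drr = numeric(), se_drr = numeric(), d = numeric(),
                      wald = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    .finish_result(res, lambda_g, est$sigma2, NA_real_, 0L, n, m, NA_real_,
                   dropped, config)
  }
  if (q == 0) {
    if (verbose) message("stage 2 selected no markers; returning empty table")
    return(empty())
  }

  # stage 3: deshrinking ridge regression on the selected markers
  if (config$ridge_prior == "genome") {
    # all panel markers are random effects: the ridge covariance is the
    # genomic covariance, H = B = lambda_g K + I, phi^2 = sigma_g^2 / s0
    # (per-marker share of the polygenic variance); everything reuses the
    # stage-1 eigendecomposition.
    s0 <- sum(colvar)                        # mean diag of Xc Xc'
    fit <- .drr_genome_fit(y, W, X[, sel, drop = FALSE], eig, lambda_g,
                           est, s0, config$dk_floor)
  } else {
    if (isTRUE(config$drr_on_whitened)) {
      wmod <- .whitener_from_B_eig(K, lambda_g, eig$vectors,
                                   lambda_g * pmax(eig$values, 0) + 1)
      wh <- whiten(wmod, y, W, X[, sel, drop = FALSE])
      y3 <- wh$y_c; W3 <- wh$W_c; Z3 <- wh$Z_c
    } else {
      y3 <- y; W3 <- W; Z3 <- X[, sel, drop = FALSE]
    }
    fit <- drr_fit(y3, W3, Z3, bounds = config$lambda_bounds,
                   dk_floor = config$dk_floor)
  }
  denom <- if (config$bonferroni == "model_markers") fit$q else m
  calls <- call_significant(fit$p_value, denom, config$alpha)
  if (verbose)
    message(sprintf(
      "stage 3: phi2 = %.4g, sigma2 = %.4g; %d significant at p < %.3g",
      fit$phi2, fit$sigma2, length(calls$detected), calls$threshold))
  res <- data.frame(
    marker = colnames(X)[sel] %||% sprintf("M%05d", sel),
    index = sel,
    r = scan$r[sel],
    p_screen = scan$p[sel],
    gamma_orr = fit$gamma_orr,
    gamma_drr = fit$gamma_drr,
    se_drr = sqrt(fit$var_drr),
    d = fit$d,
    wald = fit$wald,
    p_value = fit$p_value,
    significant = seq_len(q) %in% calls$detected,
    stringsAsFactors = FALSE)
  .finish_result(res, lambda_g, est$sigma2, fit$phi2, q, n, m,
                 calls$threshold, dropped, config)
}

.finish_result <- function(res, lambda_g, sigma2, phi2, q, n, m, threshold,
                           dropped, config) {
  attr(res, "lambda_g") <- lambda_g
  attr(res, "sigma2") <- sigma2
  attr(res, "phi2") <- phi2
  attr(res, "q") <- q
  attr(res, "n") <- n
  attr(res, "m") <- m
  attr(res, "threshold") <- threshold
  attr(res, "dropped_samples") <- dropped
  attr(res, "config") <- config
  class(res) <- c("fastrr_result", "data.frame")
  res
}

#' @export
print.fastrr_result <- function(x, ...) {
  cat(sprintf(
    "fastrr_result: n = %d, m = %d, lambda_g = %.4g, q = %d selected\n",
    attr(x, "n"), attr(x, "m"), attr(x, "lambda_g"), attr(x, "q")))
  ns <- sum(x$significant)
  if (nrow(x)) {
    cat(sprintf("  %d significant at Bonferroni threshold %.3g\n",
                ns, attr(x, "threshold")))
    if (ns) {
      sig <- x[x$significant, c("marker", "index", "gamma_drr", "se_drr",
                                "p_value")]
      print(format(sig, digits = 4), row.names = FALSE)
    }
  } else {
    cat("  empty result (no markers passed the screen)\n")
  }
  invisible(x)
}

#' Significant hits of a pipeline result
#'
#' @param result a `fastrr_result`.
#' @return integer vector of significant marker indices (genome coordinates,
#'   1-based).
#' @export
detected_indices <- function(result) {
  stopifnot(inherits(result, "fastrr_result"))
  result$index[result$significant]
}
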