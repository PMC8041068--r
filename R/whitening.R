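#' Build the polygenic/noise whitening operator
#'
#' With the variance ratio lambda_g fixed, the covariance of the polygenic
#' plus residual noise is proportional to `B = lambda_g K + I`.  The spectral
#' decomposition `B = Q Lambda Q'` yields the symmetric whitener
#' `C = Q Lambda^(-1/2) Q'`, which satisfies `C B C' = I`: after multiplying
#' the model through by C the combined noise has covariance sigma^2 I.
#'
#' @param K n x n symmetric PSD relatedness matrix.
#' @param lambda_g variance ratio sigma_g^2 / sigma^2 (>= 0).
#' @param clip eigenvalue floor applied to Lambda before the inverse square
#'   root (numerical PSD guard; in exact arithmetic all eigenvalues of B are
#'   >= 1).
#' @return A `kinship_model`: list with `K`, `lambda_g`, eigenvectors `Q`,
#'   eigenvalues `Lambda` of B, and the whitener `C`.
#' @export
build_whitener <- function(K, lambda_g, clip = 1e-8) {
  if (lambda_g < 0) stop("lambda_g must be >= 0", call. = FALSE)
  B <- lambda_g * K
  diag(B) <- diag(B) + 1
  eig <- eigen(B, symmetric = TRUE)
  .whitener_from_B_eig(K, lambda_g, eig$vectors, eig$values, clip)
}

.whitener_from_B_eig <- function(K, lambda_g, Q, Lambda, clip = 1e-8) {
  if (any(Lambda < clip))
    stop("eigenvalue of lambda_g*K + I below the clipping floor (",
         format(min(Lambda)), "); matrix not positive definite", call. = FALSE)
  C <- tcrossprod(Q %*% diag(Lambda^(-0.25), length(Lambda)))
  structure(list(K = K, lambda_g = lambda_g, Q = Q, Lambda = Lambda, C = C),
            class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat(sprintf(
    "kinship_model: n = %d, lambda_g = %.4g, eigenvalues of B in [%.4g, %.4g]\n",
    nrow(x$C), x$lambda_g, min(x$Lambda), max(x$Lambda)))
  invisible(x)
}

#' Apply the whitening transform
#'
#' Left-multiplies the phenotype, the fixed-effect design and the genotype
#' columns by the whitener C, turning the polygenic model into an ordinary
#' homoscedastic regression.
#'
#' @param model a `kinship_model` from [build_whitener()].
#' @param y phenotype vector.
#' @param W optional fixed-effect design matrix.
#' @param Z optional n x m marker matrix (whitened column-wise).
#' @return list with `y_c` and, when supplied, `W_c` and `Z_c`.
#' @export
whiten <- function(model, y, W = NULL, Z = NULL) {
  stopifnot(inherits(model, "kinship_model"))
  C <- model$C
  n <- nrow(C)
  if (length(y) != n) stop("length(y) does not match the whitener", call. = FALSE)
  out <- list(y_c = drop(C %*% y))
  if (!is.null(W)) {
    W <- as.matrix(W)
    if (nrow(W) != n) stop("nrow(W) does not match the whitener", call. = FALSE)
    out$W_c <- C %*% W
  }
  if (!is.null(Z)) {
    Z <- geno_matrix(Z)
    if (nrow(Z) != n) stop("nrow(Z) does not match the whitener", call. = FALSE)
    out$Z_c <- C %*% Z
  }
  out
}
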