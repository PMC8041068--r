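#' Marginal correlation scan
#'
#' Computes, for every marker column, the Pearson correlation r with the
#' (whitened) phenotype and the two-sided p-value of the correlation t-test,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom — the same
#' test `cor.test()` performs.  Monomorphic (zero-variance) columns get
#' `r = NA`, `p = 1` and are never selected; |r| = 1 gives p = 0.
#'
#' @param y_c numeric (whitened) phenotype vector, length n >= 3.
#' @param Z_c n x m matrix of (whitened) marker columns.
#' @param threshold selection threshold on the p-value (strict `<`),
#'   default 0.01.
#' @return A `screen_result` data frame with columns `marker`, `r`, `t`, `p`,
#'   `selected`; the threshold is kept as an attribute.
#' @export
marginal_scan <- function(y_c, Z_c, threshold = 0.01) {
  Z_c <- geno_matrix(Z_c)
  n <- length(y_c)
  if (n < 3) stop("correlation test needs n >= 3", call. = FALSE)
  if (nrow(Z_c) != n) stop("nrow(Z_c) must equal length(y_c)", call. = FALSE)
  sy <- sd(y_c)
  if (sy == 0) stop("phenotype is constant; correlations undefined", call. = FALSE)
  m <- ncol(Z_c)
  cm <- colMeans(Z_c)
  css <- colSums(Z_c^2) - n * cm^2          # centered sums of squares
  num <- drop(crossprod(Z_c, y_c - mean(y_c)))
  ok <- css > .Machine$double.eps * n * pmax(1, colSums(Z_c^2) / n)
  r <- rep(NA_real_, m)
  r[ok] <- num[ok] / sqrt(css[ok] * (n - 1) * sy^2)
  r[ok] <- pmin(1, pmax(-1, r[ok]))
  .scan_result(r, n, threshold,
               markers = colnames(Z_c) %||% sprintf("M%05d", seq_len(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared finisher: r -> t -> p -> selected (also used by the fast
# rotated-coordinates scan inside run_fastrr)
.scan_result <- function(r, n, threshold, markers) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 0))  # |r| = 1 -> t = +-Inf -> p = 0
  p <- 2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
  p[is.na(r)] <- 1
  selected <- !is.na(r) & p < threshold
  res <- data.frame(marker = markers, r = r, t = t, p = p,
                    selected = selected, stringsAsFactors = FALSE)
  attr(res, "threshold") <- threshold
  attr(res, "n") <- n
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Select screening candidates
#'
#' Returns the sorted indices of markers whose correlation-test p-value is
#' strictly below the threshold.  An empty selection is valid and is handled
#' downstream by the pipeline.
#'
#' @param scan a `screen_result` from [marginal_scan()].
#' @param threshold p-value cutoff (strict `<`), default 0.01.
#' @return sorted integer vector of candidate marker indices (possibly empty).
#' @export
select_candidates <- function(scan, threshold = 0.01) {
  stopifnot(inherits(scan, "screen_result"))
  sort(which(!is.na(scan$r) & scan$p < threshold))
}

#' @export
print.screen_result <- function(x, ...) {
  q <- sum(x$selected)
  cat(sprintf("screen_result: %d markers scanned, %d selected (p < %g)\n",
              nrow(x), q, attr(x, "threshold")))
  invisible(x)
}

#' Export a scan as TSV
#'
#' @param scan a `screen_result`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
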