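#' Simulation configuration
#'
#' Bundles all parameters of one Monte-Carlo simulation scenario: dimensions,
#' allele-frequency bounds, genotype coding, the fixed intercept (grand mean),
#' the residual variance sigma^2, the polygenic variance sigma_g^2 (the
#' covariance of the polygenic term is sigma_g^2 * K with K scaled to mean
#' diagonal 1; the c-times-K background scenarios use sigma_g^2 = c), and the
#' QTN layout (positions and true effects).
#'
#' @param n_individuals number of individuals (rows).
#' @param n_markers number of biallelic markers (columns).
#' @param maf_low,maf_high bounds of the per-marker minor allele frequency,
#'   drawn Uniform(maf_low, maf_high); require 0 < maf_low < maf_high <= 0.5.
#' @param genotype_coding `"two_class"` codes the two homozygotes -1/+1
#'   (inbred panel); `"hwe_three_class"` codes genotypes -1/0/+1 with
#'   Hardy-Weinberg frequencies (q^2, 2q(1-q), (1-q)^2) for MAF q.
#' @param grand_mean fixed intercept mu of the phenotype (phenotype units).
#' @param residual_variance residual variance sigma^2 (> 0).
#' @param polygenic_variance sigma_g^2 >= 0 (phenotype-units^2); the
#'   polygenic term is drawn MVN(0, sigma_g^2 * K).
#' @param qtn_positions integer marker indices (1-based) carrying effects.
#' @param qtn_effects numeric true additive effects, same length as
#'   `qtn_positions`.
#' @param n_replicates default replicate count for [run_experiment()].
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [sim_preset()] for the canned single-QTN / five-QTN scenarios.
#' @export
sim_config <- function(n_individuals,
                       n_markers,
                       maf_low = 0.1,
                       maf_high = 0.5,
                       genotype_coding = c("two_class", "hwe_three_class"),
                       grand_mean = 10,
                       residual_variance = 10,
                       polygenic_variance = 2,
                       qtn_positions = integer(),
                       qtn_effects = numeric(),
                       n_replicates = 100,
                       base_seed = 1L) {
  genotype_coding <- match.arg(genotype_coding)
  n_individuals <- as.integer(n_individuals)
  n_markers <- as.integer(n_markers)
  if (is.na(n_individuals) || n_individuals < 1 ||
      is.na(n_markers) || n_markers < 1)
    stop("n_individuals and n_markers must be positive integers", call. = FALSE)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  if (residual_variance <= 0)
    stop("residual_variance must be > 0", call. = FALSE)
  if (polygenic_variance < 0)
    stop("polygenic_variance must be >= 0", call. = FALSE)
  qtn_positions <- as.integer(qtn_positions)
  if (length(qtn_positions) != length(qtn_effects))
    stop("qtn_positions and qtn_effects must have equal length", call. = FALSE)
  if (anyDuplicated(qtn_positions))
    stop("qtn_positions must be distinct", call. = FALSE)
  if (length(qtn_positions) &&
      (min(qtn_positions) < 1 || max(qtn_positions) > n_markers))
    stop("qtn_positions out of range 1..n_markers", call. = FALSE)
  structure(list(
    n_individuals = n_individuals,
    n_markers = n_markers,
    maf_low = maf_low,
    maf_high = maf_high,
    genotype_coding = genotype_coding,
    grand_mean = grand_mean,
    residual_variance = residual_variance,
    polygenic_variance = polygenic_variance,
    qtn_positions = qtn_positions,
    qtn_effects = as.numeric(qtn_effects),
    n_replicates = as.integer(n_replicates),
    base_seed = as.integer(base_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation scenario:\n")
  cat(sprintf("  %d individuals x %d markers, MAF ~ U(%g, %g), coding %s\n",
              x$n_individuals, x$n_markers, x$maf_low, x$maf_high,
              x$genotype_coding))
  cat(sprintf("  mean %g, residual variance %g, polygenic variance %g\n",
              x$grand_mean, x$residual_variance, x$polygenic_variance))
  if (length(x$qtn_positions)) {
    cat(sprintf("  %d QTNs at positions %s\n", length(x$qtn_positions),
                paste(x$qtn_positions, collapse = ", ")))
    cat(sprintf("  effects: %s\n",
                paste(format(x$qtn_effects), collapse = ", ")))
  } else {
    cat("  no fixed-position QTNs\n")
  }
  invisible(x)
}

#' Canned simulation scenarios
#'
#' Standard Monte-Carlo designs for an inbred panel of n = 2000 individuals
#' and m = 10000 independent markers, phenotype mean 10 and residual variance
#' 10, under a 2x / 5x / 10x polygenic background:
#' \describe{
#'   \item{`"single-qtn"`}{one QTN at position 98 with effect 0.7398.}
#'   \item{`"five-qtn"`}{QTNs at positions 98, 301, 540, 801, 1000 with
#'     effects 0.5451, 0.8622, 0.8598, 1.0789, 1.2093.}
#'   \item{`"random-qtn"`}{100 QTN positions drawn per replicate, joint
#'     contribution to phenotypic variance 0.5 (see [random_qtn_design()]);
#'     positions/effects are drawn at generation time.}
#' }
#'
#' @param name one of `"single-qtn"`, `"five-qtn"`, `"random-qtn"`; a
#'   suffix `-2k`, `-5k` or `-10k` may select the background instead of
#'   the `background` argument (e.g. `"single-qtn-10k"`).
#' @param background polygenic variance sigma_g^2 (2, 5 or 10 for the
#'   c-times-K scenarios; any value >= 0 is accepted).
#' @param base_seed integer base seed.
#' @return A [sim_config()] object.  For `"random-qtn"` the QTN slots are
#'   empty and the attribute `random_qtn` holds `list(n_qtn, total_h2)`.
#' @export
sim_preset <- function(name, background = 2, base_seed = 1L) {
  name <- tolower(name)
  if (grepl("-(2|5|10)k$", name)) {
    background <- as.numeric(sub("^.*-([0-9]+)k$", "\\1", name))
    name <- sub("-(2|5|10)k$", "", name)
  }
  base <- list(n_individuals = 2000L, n_markers = 10000L,
               grand_mean = 10, residual_variance = 10,
               polygenic_variance = background, base_seed = base_seed)
  cfg <- switch(name,
    "single-qtn" = do.call(sim_config, c(base, list(
      qtn_positions = 98L, qtn_effects = 0.7398))),
    "five-qtn" = do.call(sim_config, c(base, list(
      qtn_positions = c(98L, 301L, 540L, 801L, 1000L),
      qtn_effects = c(0.5451, 0.8622, 0.8598, 1.0789, 1.2093)))),
    "random-qtn" = {
      x <- do.call(sim_config, base)
      attr(x, "random_qtn") <- list(n_qtn = 100L, total_h2 = 0.5)
      x
    },
    stop("unknown preset: ", name, call. = FALSE)
  )
  cfg
}
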