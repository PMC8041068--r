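# Delimited and VCF input/output.

#' Read a genotype matrix
#'
#' TSV layout: first column sample IDs, remaining columns numeric additive
#' genotype codes, header row of marker IDs.  VCF: biallelic SNP records are
#' converted to additive dosage (0/1/2 alternate-allele copies) and then to
#' centered coding (dosage - 1, i.e. -1/0/+1); multi-allelic records are
#' skipped with a message, and missing genotypes are mean-imputed per marker
#' (fraction reported).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A `genotype_matrix` (MAFs computed from the data).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") return(read_genotypes_vcf(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("genotype TSV needs sample IDs plus >= 1 marker",
                         call. = FALSE)
  ids <- as.character(dt[[1]])
  X <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(X))
    stop("non-numeric genotype entries in ", path, call. = FALSE)
  rownames(X) <- ids
  .as_genotype_matrix(X)
}

.as_genotype_matrix <- function(X, coding = "two_class") {
  maf <- apply(X, 2, function(z) {
    f <- mean((z - min(z)) / max(diff(range(z)), 1)) # frequency of the high code
    min(f, 1 - f)
  })
  structure(list(X = X, maf = maf, positions = seq_len(ncol(X)),
                 coding = coding), class = "genotype_matrix")
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    message("skipped ", n_skip, " multi-allelic record(s)")
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0)
    stop("no usable biallelic genotype records in ", path, call. = FALSE)
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0
  dosage[clean %in% c("0/1", "1/0")] <- 1
  dosage[clean == "1/1"] <- 2
  X <- t(dosage) - 1                         # samples x markers, centered coding
  miss <- mean(is.na(X))
  if (miss > 0) {
    message(sprintf("mean-imputed %.2f%% missing genotype entries", 100 * miss))
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[!nas, j])
    }
  }
  ids <- v@fix[, "ID"]
  colnames(X) <- ifelse(is.na(ids) | ids == ".",
                        paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"]), ids)
  .as_genotype_matrix(X)
}

#' Read a phenotype vector
#'
#' Two-column delimited text: sample ID, numeric value (header optional,
#' detected).
#'
#' @param path input file.
#' @return named numeric vector.
#' @export
read_phenotype <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 2) stop("phenotype file needs two columns (ID, value)",
                         call. = FALSE)
  y <- as.numeric(dt[[2]])
  if (anyNA(y)) stop("non-numeric phenotype values in ", path, call. = FALSE)
  names(y) <- as.character(dt[[1]])
  y
}

#' Read covariates
#'
#' First column sample IDs, remaining numeric covariate columns.
#' @param path input file.
#' @return numeric matrix with sample rownames.
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  M <- as.matrix(dt[, -1, drop = FALSE])
  rownames(M) <- as.character(dt[[1]])
  M
}

#' Read / write a kinship matrix
#'
#' Square delimited text with a sample-ID header row and first column.
#' @param path file path.
#' @return numeric matrix (for the reader).
#' @export
read_kinship <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  K <- as.matrix(dt[, -1, drop = FALSE])
  rownames(K) <- as.character(dt[[1]])
  if (nrow(K) != ncol(K)) stop("kinship file is not square", call. = FALSE)
  K
}

#' @rdname read_kinship
#' @param K kinship matrix to write.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(sample = rownames(K) %||% paste0("S", seq_len(nrow(K))),
                   K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline result table
#'
#' TSV with a structured `#`-prefixed header echoing the run metadata
#' (lambda_g, q, Bonferroni threshold, configuration).
#'
#' @param result a `fastrr_result`.
#' @param path output file.
#' @export
write_results <- function(result, path) {
  cfg <- attr(result, "config")
  hdr <- c(
    sprintf("# fastrr result: n=%d m=%d", attr(result, "n"), attr(result, "m")),
    sprintf("# lambda_g=%.6g sigma2=%.6g phi2=%.6g q=%d",
            attr(result, "lambda_g"), attr(result, "sigma2"),
            attr(result, "phi2"), attr(result, "q")),
    sprintf("# screen_threshold=%g alpha=%g bonferroni=%s wald_threshold=%.6g",
            cfg$screen_threshold, cfg$alpha, cfg$bonferroni,
            attr(result, "threshold")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(as.data.frame(result), con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Write simulated data as delimited fixtures
#'
#' Writes genotype TSV (rows = samples, header = marker IDs), phenotype TSV
#' (sample ID, value) and truth TSV (position, true effect).
#'
#' @param sim output of [simulate_dataset()].
#' @param prefix path prefix; writes `<prefix>_geno.tsv`, `<prefix>_pheno.tsv`,
#'   `<prefix>_truth.tsv`.
#' @return character vector of the files written, invisibly.
#' @export
write_sim_fixture <- function(sim, prefix) {
  gpath <- paste0(prefix, "_geno.tsv")
  ppath <- paste0(prefix, "_pheno.tsv")
  tpath <- paste0(prefix, "_truth.tsv")
  X <- sim$geno$X
  gd <- data.frame(sample = rownames(X), X, check.names = FALSE)
  utils::write.table(gd, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(sim$y), value = sim$y),
                     ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(position = sim$truth$qtn_positions,
                                effect = sim$truth$qtn_effects),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gpath, ppath, tpath))
}

#' Export a genotype matrix as a minimal VCF
#'
#' Two-class coding maps -1/+1 to homozygous 0/0 and 1/1; three-class coding
#' maps -1/0/+1 to 0/0, 0/1, 1/1.  Intended for round-trip I/O testing.
#'
#' @param geno a `genotype_matrix`.
#' @param path output `.vcf` path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  X <- geno_matrix(geno)
  gt <- matrix("0/1", nrow(X), ncol(X))
  gt[X == -1] <- "0/0"
  gt[X == 1] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT",
                       rownames(X) %||% paste0("S", seq_len(nrow(X)))),
                     collapse = "\t")), con)
  m <- ncol(X)
  ids <- colnames(X) %||% sprintf("M%05d", seq_len(m))
  lines <- vapply(seq_len(m), function(j)
    paste(c("1", j, ids[j], "A", "T", ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t"), "")
  writeLines(lines, con)
  invisible(path)
}
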