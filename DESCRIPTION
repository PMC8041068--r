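Package: fastrr
Title: Fast Multi-Locus Ridge Regression for Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multi-locus genome-wide association mapping by a three-stage
    ridge-regression algorithm: (1) restricted maximum likelihood estimation
    of the polygenic-to-residual variance ratio and spectral whitening of the
    polygenic plus residual covariance, (2) marginal-correlation screening of
    whitened markers against the whitened phenotype, and (3) a multi-locus
    deshrinking ridge regression on the selected candidates with Wald
    chi-square tests and Bonferroni calls.  Includes a Monte-Carlo simulation
    module for power, false-positive-rate and effect-accuracy evaluation, and
    a command-line interface for running the pipeline on genotype matrices or
    VCF files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
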