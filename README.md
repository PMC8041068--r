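# fastrr — fast multi-locus ridge regression for GWAS

`fastrr` maps quantitative-trait loci in genome-wide association studies
where the number of markers far exceeds the number of individuals, with a
focus on *minor-effect* loci that single-marker scans tend to miss.  It is
aimed at statistical geneticists working with inbred panels or natural
populations who want a multi-locus mixed-model analysis that runs in
seconds-to-minutes on n ≈ 10³ individuals × m ≈ 10⁴–10⁵ markers.

## The method

All marker effects are treated as random under the mixed linear model

    y = Wα + Zγ + u + ε,   u ~ MVN(0, σg² K),   ε ~ MVN(0, σ² I)

and the analysis runs in three stages:

1. **Whitening.** The polygenic-to-residual variance ratio
   λg = σg²/σ² is estimated once by REML on the reduced model (one
   eigendecomposition of the kinship K, 1-D optimisation), and the model
   is multiplied through by C = QΛ^(−1/2)Q′, the inverse symmetric square
   root of B = λg K + I, so the combined noise becomes σ²I.
2. **Screening.** Each whitened marker is tested for marginal Pearson
   correlation with the whitened phenotype (the classical correlation
   t-test); markers with p < 0.01 survive — permissive by design so minor
   effects are not lost.
3. **Deshrinking ridge regression (DRR).** Ridge BLUPs
   γ̂ᴼᴿᴿ = λZ′H⁻¹(y − Wα̂), H = λZZ′ + I, are deshrunk by the
   well-measurement factor dₖ = λZₖ′H⁻¹Zₖ:
   γ̂ᴰᴿᴿ = γ̂ᴼᴿᴿ/dₖ, var(γ̂ᴰᴿᴿ) = var(γ̂ᴼᴿᴿ|y)/dₖ, and each marker is
   tested with the Wald statistic Wₖ = (γ̂ᴰᴿᴿ)²/var(γ̂ᴰᴿᴿ) ~ χ²₁ at the
   Bonferroni level α/q.

The package also ships a Monte-Carlo simulation module
(`sim_config()` / `sim_preset()` / `simulate_dataset()`) and an
evaluation module (`run_experiment()`) that computes detection power,
false positive rate (in ‰) and effect-estimation accuracy across
replicates, plus a small CLI.  See the methods vignette
(`vignettes/fastrr-methods.Rmd`) for the models, numerical choices and
the scope of the stage-3 ridge prior.

## Worked example

Simulate an inbred panel of 500 individuals × 2000 independent markers
with two QTNs (effects 0.9 at position 98 and 1.2 at position 700), a
polygenic background with σg² = 2 and residual variance 10, then run the
pipeline:

```r
library(fastrr)
cfg <- sim_config(n_individuals = 500, n_markers = 2000,
                  qtn_positions = c(98L, 700L), qtn_effects = c(0.9, 1.2),
                  polygenic_variance = 2)
sim <- simulate_dataset(cfg, seed = 1)
res <- run_fastrr(sim$geno, sim$y, kinship = sim$K, verbose = TRUE)
#> stage 1: lambda_g = 0.129 (sigma2 = 12.09)
#> stage 2: 14 of 2000 markers selected (p < 0.01)
#> stage 3: phi2 = 0.0009989, sigma2 = 12.09; 6 significant at p < 0.00357
print(res)
#> fastrr_result: n = 500, m = 2000, lambda_g = 0.129, q = 14 selected
#>   6 significant at Bonferroni threshold 0.00357
#>  marker index gamma_drr se_drr   p_value
#>  M00098    98    1.1367 0.1872 1.273e-09
#>  M00217   217   -0.5123 0.1690 2.436e-03
#>  M00444   444   -0.5344 0.1779 2.671e-03
#>  M00700   700    1.0664 0.1863 1.040e-08
#>  M01184  1184   -0.5721 0.1954 3.412e-03
#>  M01883  1883   -0.5417 0.1678 1.248e-03
```

Both simulated QTNs are recovered with effect estimates near their true
values (1.14 vs 0.9 at position 98; 1.07 vs 1.2 at position 700, each
within ~1.3 standard errors); `gamma_drr` is the deshrunk per-allele
effect in phenotype units, `se_drr` its standard error, and `p_value`
the χ²₁ Wald p-value.  The remaining four calls are the kind of
chance-correlated markers a permissive screen admits at this small
problem size; at larger n and m the per-marker false positive rate falls
to the published per-mille range.  Real data enter through
`read_genotypes()` (TSV or VCF), `read_phenotype()` and optional
`read_kinship()` / `read_covariates()`, or through the CLI:

```sh
fastrr run --geno geno.tsv --pheno pheno.tsv --out result.tsv
fastrr simulate --preset five-qtn-2k --seed 7 --out sim
fastrr evaluate --preset single-qtn-10k --reps 30 --seed 1 --out summary.tsv
```

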