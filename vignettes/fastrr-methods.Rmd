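---
title: "Multi-locus GWAS by deshrinking ridge regression: models and methods"
author: "fastrr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus GWAS by deshrinking ridge regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastrr)
```

## The genetic model

For a quantitative trait measured on $n$ individuals genotyped at $m$
biallelic markers, the package works under the mixed linear model

$$
\mathbf{y} = \mathbf{W}\boldsymbol\alpha + \mathbf{Z}\gamma + \mathbf{u}
  + \boldsymbol\varepsilon,
\qquad
\mathbf{u} \sim MVN(\mathbf{0}, \sigma_g^2 \mathbf{K}),
\qquad
\boldsymbol\varepsilon \sim MVN(\mathbf{0}, \sigma^2 \mathbf{I}_n),
$$

where $\mathbf{W}\boldsymbol\alpha$ collects fixed effects (at least an
intercept), $\mathbf{Z}$ holds additively coded marker genotypes whose
effects $\gamma$ are *random*, $\mathbf{K}$ is an $n \times n$ relatedness
(kinship) matrix, $\sigma_g^2$ the polygenic variance and $\sigma^2$ the
residual variance.  Treating marker effects as random is what
distinguishes this approach from the fixed-effect single-marker scan: it
lets many small effects coexist in one model, which is where minor-effect
loci are won or lost.

The algorithm runs in three stages.

### Stage 1 — variance-ratio estimation and whitening

The reduced model without marker effects has
$\mathrm{var}(\mathbf{y}) = \sigma^2(\lambda_g \mathbf{K} + \mathbf{I})$
with $\lambda_g = \sigma_g^2/\sigma^2$.  `estimate_lambda_g()` maximises
the restricted likelihood of $\lambda_g$ after one eigendecomposition of
$\mathbf{K}$, which reduces every likelihood evaluation to $O(n)$: a
coarse log-spaced grid brackets the optimum on
$[10^{-6}, 10^{6}]$ and Brent's method refines it.  REML (rather than ML)
is used so the intercept and covariate degrees of freedom do not bias the
ratio.  $\hat\lambda_g$ is estimated once and frozen for all later stages.

With $\mathbf{B} = \hat\lambda_g \mathbf{K} + \mathbf{I} =
\mathbf{Q}\boldsymbol\Lambda\mathbf{Q}'$, the whitener is the inverse
symmetric square root $\mathbf{C} =
\mathbf{Q}\boldsymbol\Lambda^{-1/2}\mathbf{Q}'$, so that
$\mathbf{C}\mathbf{B}\mathbf{C}' = \mathbf{I}$: after multiplying the
model through by $\mathbf{C}$, the combined polygenic-plus-residual noise
is homoscedastic with variance $\sigma^2$.  Eigenvalues are floored at
$10^{-8}$ before the inverse square root as a numerical guard; in exact
arithmetic all eigenvalues of $\mathbf{B}$ are at least 1.

The kinship itself, when not supplied, is the centered cross-product
$\mathbf{K} = \mathbf{X}_c\mathbf{X}_c'/s_0$ with $s_0$ chosen so that
$\mathrm{mean}(\mathrm{diag}\,\mathbf{K}) = 1$, computed from **all**
markers including any causal ones (the standard GWAS practice).  On this
scale $\lambda_g$ is directly comparable with the simulation's polygenic
variance.

### Stage 2 — marginal-correlation screening

For every marker, the Pearson correlation between the whitened column
$\mathbf{Z}_{c,k}$ and the whitened phenotype $\mathbf{y}_c$ is tested
with the usual correlation $t$-test,
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.  Markers with
$p < 0.01$ (strict inequality) are retained.  The threshold deliberately
errs on the permissive side — at 0.01 even slight correlations survive, so
minor-effect loci are not lost at this stage, while the marker count drops
from thousands to roughly $0.01\,m$ plus the true signals.  Monomorphic
columns receive $p = 1$ and are never selected; $|r| = 1$ maps to $p = 0$.
The scan is a pair of matrix products and is evaluated in the eigenbasis
of $\mathbf{K}$ inside the pipeline (numerically identical to explicitly
whitening every column, which the test suite verifies).

### Stage 3 — deshrinking ridge regression

On the selected markers the package computes ordinary-ridge-regression
(ORR) BLUPs and their conditional variances,

$$
\hat\gamma^{ORR} = \lambda \mathbf{Z}' \mathbf{H}^{-1}
(\mathbf{y}-\mathbf{W}\hat\alpha),
\qquad
\mathbf{H} = \lambda\mathbf{Z}\mathbf{Z}' + \mathbf{I},
\qquad \lambda = \phi^2/\sigma^2,
$$

with a single shared marker-effect variance $\phi^2$.  Ridge BLUPs are
shrunken; testing them directly is miscalibrated and biased.  The
well-measurement factor
$d_k = 1 - \mathrm{var}(\hat\gamma_k^{ORR}|\mathbf{y})/\phi^2 =
\lambda \mathbf{Z}_k'\mathbf{H}^{-1}\mathbf{Z}_k$
(the effective degree of freedom of marker $k$) undoes the shrinkage:

$$
\hat\gamma_k^{DRR} = \hat\gamma_k^{ORR}/d_k,
\qquad
\mathrm{var}(\hat\gamma_k^{DRR}) = \mathrm{var}(\hat\gamma_k^{ORR}|\mathbf{y})/d_k,
\qquad
W_k = (\hat\gamma_k^{DRR})^2/\mathrm{var}(\hat\gamma_k^{DRR})
\sim \chi^2_1 \text{ under } H_0 .
$$

Markers with $d_k \le 10^{-8}$ are flagged "unmeasured" and excluded from
testing rather than silently dropped: below that floor the deshrunk
quantities are numerically meaningless.  Significance is declared at the
Bonferroni level $\alpha/q$ where $q$ is the number of markers in the
fitted model (a genome-wide denominator is available as a configuration
option).

### The scope of the ridge prior

One design question is genuinely open in stage 3: *which* markers carry
the random-effect prior when the Wald tests are formed.  The package
implements both readings.

* `ridge_prior = "genome"` (the default).  Conceptually every marker of
  the panel is a random effect, so the ridge covariance is the genomic
  covariance $\phi^2 \mathbf{Z}_{all}\mathbf{Z}_{all}' + \sigma^2\mathbf{I}$.
  After absorbing column means into the intercept this is exactly
  $\sigma^2 \mathbf{B}$, so the variance components are inherited from
  stage 1 ($\phi^2 = \hat\sigma_g^2/s_0$, the per-marker share of the
  polygenic variance) and $\mathbf{H} = \mathbf{B}$ reuses the existing
  eigendecomposition — no additional estimation.  In this regime $d_k$ is
  small and the deshrunk estimate collapses to the marginal
  generalized-least-squares estimator
  $\mathbf{Z}_{c,k}'\mathbf{B}^{-1}(\mathbf{y}-\mathbf{W}\hat\alpha) /
  \mathbf{Z}_{c,k}'\mathbf{B}^{-1}\mathbf{Z}_{c,k}$ with variance
  $\sigma^2 / \mathbf{Z}_{c,k}'\mathbf{B}^{-1}\mathbf{Z}_{c,k}$.  By a
  Sherman–Morrison argument the marker's own contribution to $\mathbf{B}$
  cancels in this ratio, so the estimate is not contaminated by its own
  prior.  We adopted this as the default because it is the reading under
  which the deshrunk effects are unbiased in our Monte-Carlo experiments:
  with the prior restricted to the selected markers, the joint fit lets
  the ~$0.01\,m$ chance-selected columns absorb part of a true QTN's
  effect, which depressed the mean recovered effect by roughly 20% in the
  single-QTN scenario while power and false-positive behaviour were
  similar.
* `ridge_prior = "model"`.  Only the $q$ selected markers carry the
  prior; $(\phi^2, \sigma^2)$ are re-estimated by REML on the selected
  design via one thin SVD (`estimate_ridge_components()`), and
  $\mathbf{H} = \lambda\mathbf{Z}_{sel}\mathbf{Z}_{sel}' + \mathbf{I}$.
  This variant is retained both as a sensitivity analysis and because the
  module-level operations (`orr_blup()`, `deshrink()`, `wald_test()`) are
  defined — and tested against dense-algebra oracles — on an arbitrary
  selected design.

Stage 3 always runs on the untransformed phenotype and genotypes; the
polygenic structure enters through the ridge prior, not through a second
whitening pass (`drr_on_whitened` exists for sensitivity analysis of the
`"model"` variant).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `screen_threshold` | 0.01 | p-value | stage-2 retention; 0.05 floods stage 3, 0.001 starts to lose minor loci |
| `alpha` | 0.05 | probability | family-wise level of the Wald calls |
| `bonferroni` | `model_markers` | — | denominator $q$ (markers in the model) vs genome-wide $m$ |
| `ridge_prior` | `genome` | — | scope of the stage-3 random-effect prior (above) |
| `dk_floor` | $10^{-8}$ | — | stability floor for the well-measurement factor |
| `lambda_bounds` | $[10^{-6}, 10^{6}]$ | — | search interval of both variance-ratio optimisations |

A consequence of the per-model Bonferroni denominator worth knowing: under
a complete null, the expected number of significant markers per run is
approximately `alpha / screen_threshold` (= 5 at the defaults),
independent of $m$, because the denominator $q$ scales with $m$.  The
per-marker false positive *rate* still falls as $1/m$ and sits near
0.5 per mille at $m = 10^4$.

## What the synthetic-data generator emulates

`generate_genotypes()` draws independent biallelic markers with MAF
$\sim U(0.1, 0.5)$.  The default `two_class` coding ($\pm 1$, an inbred
panel with only the two homozygotes, marker variance $4p(1-p)$) is the
coding consistent with the effect sizes used in the canned scenarios; a
`hwe_three_class` coding ($-1/0/+1$ with Hardy–Weinberg frequencies) is
available.  `generate_phenotype()` adds a fixed grand mean (default 10),
QTN effects at fixed positions, a polygenic draw
$MVN(\mathbf{0}, \sigma_g^2\mathbf{K})$ with $\mathbf{K}$ derived from the
simulated markers themselves, and Gaussian noise ($\sigma^2 = 10$).

The canned scenarios (`sim_preset()`) use $n = 2000$, $m = 10^4$: a
single QTN of effect 0.7398 at position 98, or five QTNs (0.5451–1.2093)
at positions 98–1000, under polygenic variances $\sigma_g^2 \in
\{2, 5, 10\}$ ("2×K / 5×K / 10×K" backgrounds, i.e. polygenic covariance
$c\,\mathbf{K}$ with $\mathbf{K}$ scaled to mean diagonal 1).  We pin the
*effect sizes*, not nominal per-QTN heritabilities: no single closed-form
effect-to-$r^2$ mapping reproduces all the quoted heritability labels, so
the printed effects are treated as the ground truth.  The absolute
(rather than $c\,\sigma^2$) reading of the background multiplier is the
one consistent with the published per-scenario estimator dispersions and
detection powers; both readings are expressible since
`polygenic_variance` is a plain parameter.

The generator deliberately omits linkage disequilibrium, population
structure, missing genotypes and non-Gaussian noise.  Passing tests on
these data therefore demonstrate correctness of the estimation and
testing machinery under the model's own assumptions — not robustness to
LD (where exact-position power is the wrong metric; `window` exists for
that), confounding, or heavy-tailed traits.

One replicate means fresh genotypes *and* phenotype; replicate $r$ of a
scenario uses seed `base_seed + r`, with the phenotype stream offset by
$10^7$ so genotype and noise draws never share a seed.  `random-qtn`
layouts re-draw 100 positions per replicate and scale effects so the
QTNs' joint contribution to the phenotypic variance is exactly 0.5 on the
realized genotype variances (equal variance shares by default — the split
is not prescribed — with random signs).

## Numerical choices

* Both 1-D REML optimisations work on $\log\lambda$: a 25-point
  log-spaced grid brackets the mode, Brent refines it, and the better of
  grid argmax and refined optimum is kept (the profile can be flat near
  the boundary).  Boundary hits are flagged with a warning; a lower-bound
  hit means "no usable variance" and, under the genome prior, leads to all
  markers being flagged unmeasured rather than producing pseudo-tests.
* Stage-3 "model" REML uses one thin SVD of $\mathbf{Z}_{sel}$; all
  downstream BLUP/deshrinkage algebra is $O(nq)$ per evaluation and is
  valid in both the $q < n$ and $q > n$ regimes.
* The kinship is accumulated as
  $\mathbf{X}\mathbf{X}' - \mathbf{a}\mathbf{1}' - \mathbf{1}\mathbf{a}'
  + (\mu'\mu)\mathbf{1}\mathbf{1}'$ (rank-one corrections,
  $\mathbf{a} = \mathbf{X}\mu$) to avoid materialising a centered copy of
  the genotype matrix.
* The Cholesky factorisation used to draw polygenic values adds a relative
  jitter of $10^{-8}$ to the diagonal because a marker-derived
  $\mathbf{K}$ is rank-deficient by one after column centering.
* Ties/degeneracies: screening $p$-values equal to the threshold are *not*
  selected (strict inequality); zero-variance markers are skipped with
  $p = 1$; an empty stage-2 selection short-circuits to an empty result
  table rather than an error.

## Problem sizes used in the checks

The replicated experiments shipped with the package run the full published
problem size ($n = 2000$, $m = 10^4$) with 30 replicates per scenario (50
for the five-QTN 10×K case), which reproduces detection powers to
binomial accuracy and effect means to about $2\,SD/\sqrt{30}$.  Unit and
property tests use $n$ of a few hundred and $m$ up to $10^4$ where the
property is distributional (null screening calibration, Wald
$\chi^2_1$ agreement at 2000 draws) and tiny dense-algebra instances
where the property is algebraic (explicit-inverse ORR oracle, the two
$d_k$ formulas, the single-marker DRR = OLS identity, grid-search REML
dominance).

## Known limitations

* Exactly one polygenic variance component; no dominance or epistasis
  kinships, no leave-one-chromosome-out correction.
* The screen is a single marginal pass — no iterated sure-independence
  screening or conditional screening.
* With LD-bearing real data the exact-position detection criterion in
  `run_experiment()` is conservative; use `window`.
* Population-structure covariates are accepted through `covariates` but
  not estimated; missing genotypes in VCF input are mean-imputed per
  marker.
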