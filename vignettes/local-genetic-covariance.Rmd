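---
title: "Estimating local genetic covariance from GWAS summary statistics"
author: "localgcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating local genetic covariance from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide genetic correlation summarizes the average concordance of
genetic effects on two traits, but the sharing is rarely uniform along
the genome: two traits can be driven by the same variants in one region
and by antagonistic ones in another. `localgcov` estimates the *local*
genetic covariance of two traits — the covariance of per-SNP genetic
effects restricted to one LD block — from nothing more than two GWAS
summary-statistics files, a reference genotype panel, and a partition of
the genome into approximately independent LD blocks, and aggregates the
same machinery into a genome-wide (global) estimate.

Two features of summary data make this hard. First, within an LD block
the z scores of nearby SNPs are strongly correlated, so per-SNP
statistics cannot be treated as independent observations. Second, the
two GWAS usually share participants; overlapping samples induce
correlation between the studies' test statistics that mimics genetic
covariance.

## Model

Standardized trait values follow additive models `phi1 = X beta + eps`
and `phi2 = Y gamma + delta` with per-SNP effects drawn jointly:
variances `h2_1/m`, `h2_2/m` and cross-trait covariance `rho/m` per SNP
(restricted to a region for the local quantity). With `n_s` shared
samples whose non-genetic effects have covariance `rho_e`, the z-score
vectors of a block with LD matrix `V` satisfy

```
Cov(z1, z2) = sqrt(n1 n2) rho_i / m_i * V^2  +  a * V,
a = n_s * rho_t / sqrt(n1 n2),   rho_t = sum_i rho_i + rho_e .
```

The nuisance term `a` captures everything sample overlap does to the
cross-study statistics; crucially it multiplies `V` while the signal
multiplies `V^2`, which is what makes the two separable.

## Estimator

Within block `i` the package

1. eigen-decomposes the reference-panel LD matrix, `V = U W U'`;
2. rotates both z vectors, `zt = U' z`, whose per-component products
   have mean `sqrt(n1 n2) rho_i / m_i * w^2 + a * w`;
3. estimates `a` once, genome-wide, as the free intercept of the
   cross-trait LD score regression of `z1_j z2_j` on
   `sqrt(n1 n2) ldscore_j / m` (weights `1/max(ldscore, 1)`; delete-one
   block jackknife over 200 contiguous blocks for its variance) — the
   intercept is never constrained, so no knowledge of `n_s` is needed;
4. subtracts the overlap contribution, `eta_j = zt1_j zt2_j - a w_j`,
   and fits a no-intercept weighted regression of `eta` on `w^2` over
   the leading `K` components, with weights `1/q2_j` where
   `q2_j = (n1 h2_1i/m_i w_j^2 + w_j)(n2 h2_2i/m_i w_j^2 + w_j)` and
   the local heritabilities come from a method-of-moments fit of
   `E[zt_j^2] = (n h2/m_i) w_j^2 + w_j` on the same leading components;
5. chooses `K` adaptively: for `K` from 10 up to
   `min(m_i, n_ref)` it evaluates `v(K)`, the larger of the theoretical
   variance (known-weights formula) and the empirical (residual-based)
   variance of the estimate, and keeps the minimizing `K` (smallest on
   ties). Rank is additionally capped at the numerical rank of the
   block;
6. reports the estimate, a variance combining the residual-based
   conditional variance with the first-order propagation of `Var(a)`
   (law of total variance), a two-sided normal p value, local
   heritabilities, and — when both heritabilities are positive — the
   local correlation `rho / sqrt(h2_1i h2_2i)` with a delta-method SE
   treating the three estimates as independent.

For the global estimate the genome is treated as a single region whose
LD matrix is block diagonal: all blocks' decorrelated components
(each block capped at its usable rank) are pooled, sorted by
eigenvalue, and one adaptive `K` is selected with the same `v(K)` rule
(long grids are thinned to ~512 evaluation points). We chose this
single-region selection over reusing the per-block `K_i` because the 50
noisy per-block selections are each correlated with their own residuals
and measurably shrink the pooled slope (about −8% at covariance 0.25 at
the simulation scales below), while one pooled selection does not.

Case-control traits are handled analytically: observed-scale covariance
equals liability-scale covariance times
`phi(t1) phi(t2) sqrt(P1(1-P1)P2(1-P2)) / [K1(1-K1)K2(1-K2)]` with `t`
the liability threshold of the population prevalence `K` and `P` the
sample prevalence; the constant is positive, so significance and sign
are scale-free.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mafMin` | 0.05 | minimum reference MAF (QC) |
| MHC window | chr6:25–35 Mb | excluded region (configurable); the usual hg19 convention |
| `kMin` | 10 | lower end of the adaptive K grid; blocks smaller than this use all components |
| `kMax` | `n_ref` | upper rank bound (503 for the usual European reference panel) |
| `nJackBlocks` | 200 | jackknife blocks for `Var(a)` |
| `ldWindowBp` | 1 Mb | physical window of the LD scores, with the unbiased small-sample `r^2` adjustment |

Strand-ambiguous SNPs are A/T and C/G pairs; both studies are aligned
to the reference panel's allele coding before estimation.

## The simulator

`simConfig()` + `simulationEngine()` + `replicateExperiment()` generate
and evaluate complete synthetic studies: block-structured genotype
panels, bivariate per-SNP effects, phenotypes with configurable sample
overlap and shared non-genetic noise (`rhoE`), and score-statistic z
values `z = X' phi / sqrt(n)`. Phenotypes are divided by their
empirical SD so the unit-variance assumption of that approximation
holds exactly. Genotype panels are held fixed across replicates (as
when simulating on real cohort genotypes); effects and noise are
redrawn per replicate, with replicate `r` seeded as
`seed + 7919 r mod (2^31 - 1)`. Because effect draws consume their
normals in a fixed order, configurations differing only in the
covariance parameter share randomness under a common seed (common
random numbers), which makes grid comparisons much sharper and couples
their deviations.

Haplotypes follow a first-order chain: each SNP copies its left
neighbor's allele distributionally, targeting adjacent correlation
`ldR` (a range assigns per-block levels evenly across it, descending,
so the first block — the default covariance target — is the
strongest-LD block, as local-covariance studies typically interrogate
large, strongly structured regions). Margins are exact Bernoulli(MAF);
the target correlation is clamped per pair to the feasibility bound
`(min(p,q) - pq)/sqrt(pq(1-p)(1-q))`, which binds when adjacent MAFs
differ. `mafProfile = "smooth"` sorts MAFs within blocks so the bound
rarely binds and blocks acquire the spike-dominated spectra of real LD.

What the generator does **not** emulate: realistic allele-frequency
spectra, long-range LD, population structure, and the heavy-tailed
block-size distribution of real LDetect partitions. Passing tests
therefore demonstrate the estimator's statistical properties under a
correct model at desk scale, not its behavior on any particular real
cohort.

## Problem sizes and what the checks show

The default configuration is the reference null design: 2402 SNPs in
12 blocks with a 400-SNP target block, `n1 = n2 = 4000`, heritability
0.5 per trait spread evenly, 503 reference samples, homogeneous
moderate LD. Under it the local test's type-I error at nominal 0.05 is
checked against the two-sided 95% binomial interval over 1000
replicates.

Grid recoveries use a genome of 2400 SNPs in 50 blocks of 48 with the
first block as target: local covariance grid 0–0.005 at
`n1 = n2 = 1000`, global grid 0–0.25 at `n1 = n2 = 2000` with smooth
MAF profiles and `ldR = c(0.4, 0.95)`, each under no/50%/100% sample
overlap (overlap scenarios add `rhoE = 0.2`), 150–200 replicates per
point. These sizes keep the per-SNP signal `n h2 / m` within an order
of magnitude of real GWAS while the whole suite runs on one CPU in
minutes; the 2-MC-SE bias bands are then honest about what desk scale
can resolve.

## Numerical choices and degenerate inputs

* Eigenvalues are clipped at zero; components below `1e-8` of the top
  eigenvalue count as numerically null and are never used.
* Negative method-of-moments heritabilities are clipped at zero inside
  the weights; the raw value is kept for reporting and for genome-wide
  aggregation (floored at `1e-6` only when normalizing the global
  correlation).
* The empirical variance needs `K >= 3`; blocks capped below that fall
  back to the theoretical variance.
* Ties in `argmin v(K)` resolve to the smallest `K`.
* Blocks with fewer than 2 usable SNPs, or where no candidate `K`
  yields a finite criterion, are reported with a status code instead of
  an estimate; the run manifest reconciles statuses with the results
  table.
* A zero total variance makes the Wald p value undefined (`NA`, with a
  warning) rather than 0 or 1.

## Known limitations

* **Desk-scale intercept absorption.** The cross-trait regression's LD
  scores are estimated from the same 503-sample panel; their
  measurement noise attenuates the slope and leaks a small positive
  bias (~+0.02 at 2400 SNPs) into the intercept, which translates into
  a few-percent multiplicative shrinkage of large global covariance
  estimates. The effect scales away with the SNP count and is
  negligible at real-data scale (hundreds of thousands of SNPs).
* **Reference-eigenvalue overdispersion.** When a block's true LD is
  weak relative to `m_block/n_ref`, reference eigenvalues overdisperse
  and the regression on `w^2` attenuates; the adaptive `K` mitigates
  but does not remove this. Strongly structured (spiked) blocks — the
  realistic case — are essentially unaffected.
* **SE calibration in strong-LD small blocks.** Imperfect decorrelation
  (reference vs. cohort LD) leaves positive cross-component covariance
  that the independence-based variance formulas ignore; at desk scale
  this can inflate the local type-I error to ~0.10 in small,
  very strong-LD target blocks. At the default design the test is
  calibrated.
* Local genetic **correlation** divides by noisy local heritabilities
  and is numerically unstable when they are small; covariance is the
  primary inference surface, and correlation is reported only when both
  heritabilities are positive.
* The delta-method SE of the correlation assumes independence of the
  three plug-in estimates.

## A minimal run

```{r example}
library(localgcov)

## simulate a study pair and estimate it back
cfg <- simConfig(n1 = 800, n2 = 800, nRef = 250,
                 blockSizes = rep(40L, 6L), rhoLocal = 0.003,
                 ldR = c(0.4, 0.8), seed = 19)
sp <- simulateStudyPair(cfg, dir = "sim")
res <- runEstimate(sp$paths$sumstats1, sp$paths$sumstats2,
                   sp$paths$bfile, sp$paths$partition,
                   out = "sim/run", global = TRUE, nJackBlocks = 40)
res$results[, c("chrom", "start", "m", "K", "rho", "var", "p")]
res$global
```
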