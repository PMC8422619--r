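# localgcov

Local and genome-wide genetic covariance between two complex traits,
estimated from GWAS summary statistics alone — robust to unknown sample
overlap between the two studies.

Genome-wide genetic correlation averages the concordance of genetic
effects over the whole genome and hides regions where two traits share
variants with opposite effect directions. `localgcov` estimates the
genetic covariance ρ<sub>i</sub> of two traits *restricted to each LD
block i* of a genome partition, together with a variance, a p value and
(when the local heritabilities support it) the local genetic
correlation ρ<sub>i</sub>/√(h²₁ᵢh²₂ᵢ).

For whom: statistical geneticists with two munged GWAS summary files
(`SNP A1 A2 Z N`), a PLINK reference panel for LD, and an LDetect-style
block partition.

## Method in brief

For z-score vectors of a block with LD matrix V (from the reference
panel),

    Cov(z1, z2) = sqrt(n1 n2) ρ_i / m_i · V² + a · V ,
    a = n_s ρ_t / sqrt(n1 n2)

where the nuisance `a` absorbs everything that `n_s` overlapping
samples with total phenotypic covariance ρ_t do to the cross-study
statistics. The package (i) estimates `a` genome-wide as the free
intercept of the cross-trait LD score regression (block-jackknife
variance; never constrained, so `n_s` need not be known); (ii) rotates
each block's z scores into the eigenbasis of V, where the component
products have mean `sqrt(n1 n2) ρ_i/m_i · w² + a·w`; (iii) subtracts
`a·w` and fits a no-intercept weighted regression on w² over the
leading K eigen-components, with K chosen adaptively by minimizing the
larger of the theoretical and the residual-based variance of the
estimate (K from 10 up to the reference sample size); (iv) combines the
conditional variance with the propagated intercept variance by the law
of total variance and reports a two-sided normal p value. The global
covariance treats the genome as one block-diagonal region with a single
pooled adaptive K. Case-control (observed-scale) estimates convert to
the liability scale by a closed-form positive constant, so significance
and sign are scale-free.

A forward simulator (correlated-genotype panels, bivariate polygenic
effects, configurable overlap and shared non-genetic noise) generates
complete synthetic study pairs and evaluates type-I error, power, bias
and RMSE of the estimator.

## Worked example

Simulate a study pair under the default desk-scale design (2402 SNPs in
12 blocks, a 400-SNP target block with local covariance 0.004, n₁ = n₂
= 4000, h² = 0.5 each, no sample overlap), then estimate everything
back from the files on disk:

```r
library(localgcov)
cfg <- simConfig(rhoLocal = 0.004, seed = 7)
sp  <- simulateStudyPair(cfg, dir = "sim")
res <- runEstimate(sp$paths$sumstats1, sp$paths$sumstats2,
                   sp$paths$bfile, sp$paths$partition,
                   out = "sim/run", global = TRUE)
res$results[, c("chrom", "start", "m", "K", "rho", "var", "p")]
```

```
   chrom   start   m  K      rho      var     p
1      2 1.0e+07 400 23 -0.01247 2.88e-04 0.463
2      2 2.0e+07 180 24  0.00236 1.42e-04 0.843
3      2 3.0e+07 181 88 -0.00597 3.12e-04 0.735
...
12     2 1.2e+08 181 11 -0.00604 1.04e-04 0.553
```

Each row is one partition block: `m` SNPs used, adaptively selected
rank `K`, local covariance `rho` with variance `var` and its two-sided
p value. Row 1 is the target block: the estimate −0.012 sits within one
standard error (√2.9e-4 ≈ 0.017) of the simulated truth 0.004 — at this
sample size a single replicate is noisy, which is exactly what `var`
reports. The overlap intercept and the pooled global estimate:

```r
res$intercept
#> CrossTraitIntercept: a = 0.3007 (var 0.495, 200 jackknife blocks)
res$global$rho        #> -0.0664   (p = 0.669)
sum(res$results$rho)  #> -0.0638   # sums of local track the global
```

`runEstimate` also writes `sim/run.results.tsv` (one row per block),
`sim/run.global.tsv` and a JSON run manifest with QC attrition, the
intercept, and a status for every block.

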