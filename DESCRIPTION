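Package: localgcov
Title: Local and Global Genetic Covariance from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates local (per LD-block) and genome-wide genetic
    covariance and correlation between two complex traits from GWAS
    summary statistics and an external genotype reference panel. Local
    z scores are decorrelated with eigenvectors of the block LD matrix,
    the number of retained eigen-components is chosen adaptively by
    minimizing the larger of the theoretical and empirical variance of
    the estimator, and unknown sample overlap between the two studies
    is absorbed by the intercept of a cross-trait LD score regression.
    Includes a forward simulator of correlated-genotype panels,
    bivariate polygenic phenotypes with configurable heritability,
    local or global covariance and sample overlap, used to validate
    calibration, power and bias of the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
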