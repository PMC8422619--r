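#' @import methods
#' @importFrom stats coef cor dnorm lm median pnorm qnorm quantile rbinom rnorm
#'   runif sd setNames var p.adjust
#' @importFrom utils read.table write.table head packageVersion
NULL

#' Two harmonized GWAS summary-statistics sets
#'
#' Container for a pair of GWAS z-score vectors restricted to a shared,
#' quality-controlled SNP set, with effect alleles of study 2 matched
#' (sign-flipped where swapped) to study 1 and both aligned to the reference
#' panel's allele coding.
#'
#' @slot snps data.frame with columns \code{snp}, \code{chrom}, \code{pos},
#'   \code{z1}, \code{z2}, one row per retained SNP, ordered by genome
#'   position.
#' @slot n1,n2 scalar GWAS sample sizes of the two studies.
#' @slot dropped named integer vector of per-filter attrition counts.
#' @export
setClass("HarmonizedPair",
  representation(snps = "data.frame", n1 = "numeric", n2 = "numeric",
                 dropped = "integer"),
  validity = function(object) {
    req <- c("snp", "chrom", "pos", "z1", "z2")
    if (!all(req %in% names(object@snps)))
      return(paste("snps must have columns", paste(req, collapse = ", ")))
    if (nrow(object@snps) < 1L) return("no SNPs retained (m must be > 0)")
    if (!all(is.finite(object@snps$z1)) || !all(is.finite(object@snps$z2)))
      return("z scores must be finite")
    if (object@n1 <= 0 || object@n2 <= 0) return("sample sizes must be positive")
    TRUE
  })

#' Eigen-system of a block LD matrix
#'
#' Eigenvalues and eigenvectors of the LD (genotype correlation) matrix of
#' one approximately independent genome block, estimated from a reference
#' panel. Eigenvalues are sorted in decreasing order and clipped at zero;
#' components beyond the numerical rank or beyond the reference sample size
#' are not usable for estimation (\code{rankCap}).
#'
#' @slot values numeric eigenvalues, nonincreasing, \code{>= 0}.
#' @slot vectors orthonormal eigenvector matrix (columns match values).
#' @slot m number of SNPs in the block.
#' @slot rankCap upper bound on usable components,
#'   \code{min(m, n_ref, numerical rank)}.
#' @export
setClass("LDBlockEigen",
  representation(values = "numeric", vectors = "matrix", m = "integer",
                 rankCap = "integer"),
  validity = function(object) {
    if (is.unsorted(rev(object@values), strictly = FALSE))
      return("eigenvalues must be nonincreasing")
    if (any(object@values < 0)) return("eigenvalues must be >= 0")
    if (ncol(object@vectors) != length(object@values))
      return("vectors/values dimension mismatch")
    if (object@rankCap > length(object@values))
      return("rankCap exceeds number of components")
    TRUE
  })

#' Cross-trait LD score regression intercept
#'
#' Estimate of the sample-overlap nuisance term
#' \eqn{a = n_s \rho_t / \sqrt{n_1 n_2}} (shared-sample count times total
#' phenotypic covariance of overlapping individuals, scaled by the study
#' sizes) obtained as the intercept of the cross-trait LD score regression,
#' with a delete-one-block jackknife variance.
#'
#' @slot estimate intercept estimate \eqn{\hat a}.
#' @slot variance jackknife variance of \eqn{\hat a}.
#' @slot slope regression slope (genome-wide covariance, by-product).
#' @slot nBlocks number of jackknife blocks used (0 if variance fixed).
#' @export
setClass("CrossTraitIntercept",
  representation(estimate = "numeric", variance = "numeric",
                 slope = "numeric", nBlocks = "integer"),
  validity = function(object) {
    if (!is.finite(object@variance) || object@variance < 0)
      return("variance must be finite and >= 0")
    TRUE
  })

#' Configuration of a forward simulation
#'
#' Generative parameters for synthetic genotype panels, bivariate polygenic
#' effects, phenotypes with optional sample overlap and correlated
#' non-genetic noise, and marginal-association z scores. The genome is a
#' set of mutually independent LD blocks; in \code{mode = "local"} genetic
#' effects of the two traits are correlated only inside the designated
#' target block (total within-block covariance \code{rhoLocal}), in
#' \code{mode = "global"} the per-SNP covariance is \code{rhoGlobal/m}
#' genome-wide.
#'
#' @slot n1,n2 cohort sizes; \code{ns} shared samples (first \code{ns} rows
#'   of each cohort are the same individuals).
#' @slot nRef reference-panel size used for LD estimation.
#' @slot blockSizes integer SNP counts of the LD blocks;
#'   \code{targetBlock} indexes the block carrying local covariance.
#' @slot mafRange range minor-allele frequencies are drawn from.
#' @slot ldR target adjacent-SNP haplotype correlation of the first-order
#'   genotype chain; a length-2 range assigns per-block levels evenly
#'   spaced across it, giving the heterogeneous local LD (and hence
#'   LD-score spread) that identifies the cross-trait regression. Each
#'   pairwise target is clamped to the Bernoulli feasibility bound.
#' @slot h2 length-2 trait heritabilities.
#' @slot rhoLocal,rhoGlobal genetic covariance (local total / global total).
#' @slot rhoE covariance of non-genetic effects on shared samples.
#' @slot mafProfile \code{"jitter"} (independent per-SNP MAFs) or
#'   \code{"smooth"} (MAFs sorted within each block). Smooth profiles
#'   keep adjacent MAFs similar, so the chain can reach strong target
#'   correlations (the Bernoulli feasibility bound binds less) and blocks
#'   acquire the spike-dominated spectra of real LD.
#' @slot seed master seed; all randomness derives from it.
#' @export
setClass("SimulationConfig",
  representation(n1 = "integer", n2 = "integer", ns = "integer",
                 nRef = "integer", blockSizes = "integer",
                 targetBlock = "integer", mafRange = "numeric",
                 ldR = "numeric", h2 = "numeric", rhoLocal = "numeric",
                 rhoGlobal = "numeric", rhoE = "numeric", mode = "character",
                 mafProfile = "character", seed = "integer"),
  validity = function(object) {
    m <- sum(object@blockSizes)
    if (m < 2L) return("need at least 2 SNPs")
    if (object@ns > min(object@n1, object@n2))
      return("ns cannot exceed min(n1, n2)")
    if (object@ns < 0L) return("ns must be >= 0")
    if (any(object@h2 < 0) || any(object@h2 > 1))
      return("heritabilities must lie in [0, 1]")
    if (!length(object@ldR) %in% c(1L, 2L) ||
        any(object@ldR < 0) || any(object@ldR >= 1))
      return("ldR must be a value or range in [0, 1)")
    if (!object@mode %in% c("local", "global"))
      return("mode must be 'local' or 'global'")
    if (!object@mafProfile %in% c("jitter", "smooth"))
      return("mafProfile must be 'jitter' or 'smooth'")
    if (object@targetBlock < 1L ||
        object@targetBlock > length(object@blockSizes))
      return("targetBlock out of range")
    if (length(object@seed) != 1L || is.na(object@seed))
      return("a scalar seed is mandatory")
    ## per-SNP cross-trait covariance must keep the effect covariance PSD
    mt <- object@blockSizes[object@targetBlock]
    perSnp <- if (object@mode == "local") object@rhoLocal / mt
              else object@rhoGlobal / m
    if (abs(perSnp) > sqrt(prod(object@h2)) / m + 1e-12)
      return("|rho| exceeds sqrt(h2_1*h2_2) on the per-SNP scale")
    se <- sqrt(prod(1 - object@h2))
    if (abs(object@rhoE) > se + 1e-12)
      return("|rhoE| exceeds sqrt((1-h2_1)(1-h2_2))")
    TRUE
  })

setMethod("show", "HarmonizedPair", function(object) {
  cat("HarmonizedPair:", nrow(object@snps), "SNPs |",
      "n1 =", object@n1, " n2 =", object@n2, "\n")
  if (length(object@dropped))
    cat("  dropped:", paste(names(object@dropped), object@dropped,
                            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LDBlockEigen", function(object) {
  cat("LDBlockEigen:", object@m, "SNPs, rank cap", object@rankCap,
      "| leading eigenvalues:",
      paste(signif(head(object@values, 3), 4), collapse = ", "), "...\n")
})

setMethod("show", "CrossTraitIntercept", function(object) {
  cat(sprintf("CrossTraitIntercept: a = %.4g (var %.3g, %d jackknife blocks)\n",
              object@estimate, object@variance, object@nBlocks))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", sum(object@blockSizes), "SNPs in",
      length(object@blockSizes), "blocks | n1 =", object@n1,
      "n2 =", object@n2, "ns =", object@ns, "| mode =", object@mode, "\n")
})

#' @describeIn HarmonizedPair number of retained SNPs
#' @param pair a \code{HarmonizedPair}
#' @export
nSnps <- function(pair) nrow(pair@snps)

#' @describeIn HarmonizedPair the per-SNP table (snp, chrom, pos, z1, z2)
#' @export
snpTable <- function(pair) pair@snps

#' @describeIn HarmonizedPair the two study sample sizes
#' @export
sampleSizes <- function(pair) c(n1 = pair@n1, n2 = pair@n2)

#' @describeIn CrossTraitIntercept intercept estimate
#' @param x a \code{CrossTraitIntercept}
#' @export
interceptEstimate <- function(x) x@estimate

#' @describeIn CrossTraitIntercept jackknife variance of the intercept
#' @export
interceptVariance <- function(x) x@variance

#' @describeIn LDBlockEigen eigenvalues
#' @param eig an \code{LDBlockEigen}
#' @export
eigenValues <- function(eig) eig@values

#' @describeIn LDBlockEigen eigenvector matrix
#' @export
eigenVectors <- function(eig) eig@vectors
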