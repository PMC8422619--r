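## Forward simulator: synthetic correlated-genotype panels (first-order
## haplotype chains within independent blocks), bivariate polygenic
## effects, phenotypes with configurable sample overlap and correlated
## non-genetic noise, and marginal-association z scores. Used to validate
## type-I error, power, bias and RMSE of the covariance estimator.

#' Build a simulation configuration
#'
#' Defaults encode the reference study conditions at desk scale: 2402
#' SNPs in 12 independent LD blocks with a 400-SNP target block, cohorts
#' of 4000, a 503-sample reference panel, per-trait heritability 0.5
#' spread evenly over all SNPs, homogeneous moderate LD (target adjacent
#' haplotype correlation 0.5) and MAFs uniform on (0.05, 0.5). Grid
#' evaluations of the estimator typically switch to a heterogeneous LD
#' range (e.g. \code{ldR = c(0.4, 0.85)}) so LD scores vary genome-wide.
#'
#' @param n1,n2 cohort sizes; \code{ns} shared samples (the first
#'   \code{ns} individuals of each cohort are identical).
#' @param nRef reference-panel size.
#' @param blockSizes SNP counts per block; \code{targetBlock} the block
#'   carrying local covariance.
#' @param mafRange MAF range of the generator.
#' @param ldR target adjacent-SNP haplotype correlation; a length-2 range
#'   spreads per-block LD levels evenly across it (heterogeneous local
#'   LD, as in real genomes).
#' @param h2 length-2 heritabilities.
#' @param rhoLocal total genetic covariance inside the target block
#'   (\code{mode = "local"}; 0 elsewhere).
#' @param rhoGlobal genome-wide genetic covariance (\code{mode =
#'   "global"}).
#' @param rhoE covariance of non-genetic effects on shared samples.
#' @param mode \code{"local"} or \code{"global"}.
#' @param mafProfile \code{"jitter"} (default) or \code{"smooth"} (MAFs
#'   sorted within blocks, enabling strong realized LD).
#' @param seed mandatory master seed.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
simConfig <- function(n1 = 4000, n2 = 4000, ns = 0, nRef = 503,
                      blockSizes = c(400L, rep(182L, 11L)),
                      targetBlock = 1L, mafRange = c(0.05, 0.5),
                      ldR = 0.5, h2 = c(0.5, 0.5), rhoLocal = 0,
                      rhoGlobal = 0, rhoE = 0, mode = "local",
                      mafProfile = "jitter", seed) {
  if (missing(seed)) stop("simConfig: a seed is mandatory")
  new("SimulationConfig", n1 = as.integer(n1), n2 = as.integer(n2),
      ns = as.integer(ns), nRef = as.integer(nRef),
      blockSizes = as.integer(blockSizes),
      targetBlock = as.integer(targetBlock), mafRange = mafRange,
      ldR = ldR, h2 = h2, rhoLocal = rhoLocal, rhoGlobal = rhoGlobal,
      rhoE = rhoE, mode = mode, mafProfile = mafProfile,
      seed = as.integer(seed))
}

## genome layout implied by a config: all blocks on chromosome 2, 10 Mb
## apart, SNPs 1 kb apart
.configLayout <- function(config) {
  bs <- config@blockSizes
  blockId <- rep(seq_along(bs), bs)
  within <- sequence(bs)
  pos <- as.integer(seq_along(bs)[blockId] * 1e7 + (within - 1L) * 1000L)
  snp <- sprintf("s%05d", seq_len(sum(bs)))
  partition <- GenomicRanges::GRanges(
    seqnames = rep(2L, length(bs)),
    ranges = IRanges::IRanges(start = seq_along(bs) * 1e7,
                              end = seq_along(bs) * 1e7 + bs * 1000 - 1),
    startBp = seq_along(bs) * 1e7,
    stopBp = seq_along(bs) * 1e7 + bs * 1000)
  list(snp = snp, chrom = rep(2L, length(pos)), pos = pos,
       blockId = blockId, partition = partition,
       bim = data.frame(chrom = 2L, snp = snp, cm = 0, pos = pos,
                        a1 = "A", a2 = "G", stringsAsFactors = FALSE))
}

## per-block chain correlation levels, evenly spaced over the ldR range,
## descending with block index: block 1 (the default target) is the
## strongest-LD block, as local-covariance studies typically interrogate
## large, strongly structured LD regions
.blockLdLevels <- function(config) {
  nb <- length(config@blockSizes)
  r <- config@ldR
  if (length(r) == 1L) rep(r, nb) else seq(r[2], r[1], length.out = nb)
}

## first-order haplotype chain with exact Bernoulli margins; the target
## adjacent correlation (per block) is clamped to the feasibility bound
## (min(p,q)-pq)/sqrt(pq(1-p)(1-q)) for each pair of margins
.simHaplotypes <- function(nHap, maf, rBlock, blockId) {
  m <- length(maf)
  H <- matrix(0L, nHap, m)
  for (j in seq_len(m)) {
    p <- maf[j]
    if (j == 1L || blockId[j] != blockId[j - 1L]) {
      H[, j] <- as.integer(runif(nHap) < p)
    } else {
      q <- maf[j - 1L]
      rmax <- (min(p, q) - p * q) / sqrt(p * q * (1 - p) * (1 - q))
      rj <- min(rBlock[blockId[j]], 0.999 * rmax)
      p11 <- p * q + rj * sqrt(p * q * (1 - p) * (1 - q))
      pc1 <- p11 / q
      pc0 <- (p - p11) / (1 - q)
      prev <- H[, j - 1L]
      H[, j] <- as.integer(runif(nHap) < ifelse(prev == 1L, pc1, pc0))
    }
  }
  H
}

#' Simulate genotype panels
#'
#' Generates haplotypes by a first-order chain with target adjacent-locus
#' correlation \code{ldR} (independent across blocks), sums haplotype
#' pairs into diploid dosages, and draws the two GWAS cohorts and an
#' independent reference panel from the same process. The first
#' \code{ns} individuals of the two cohorts are the same samples.
#' Fully deterministic given the config seed.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return list \code{study1}, \code{study2}, \code{ref} (dosage
#'   matrices), \code{maf}, \code{layout}.
#' @export
simulateGenotypes <- function(config) {
  set.seed(config@seed)
  lay <- .configLayout(config)
  m <- sum(config@blockSizes)
  maf <- runif(m, config@mafRange[1], config@mafRange[2])
  if (config@mafProfile == "smooth")
    maf <- stats::ave(maf, lay$blockId, FUN = sort)
  nPool <- config@n1 + config@n2 - config@ns
  rBlock <- .blockLdLevels(config)
  pool <- .simHaplotypes(2L * nPool, maf, rBlock, lay$blockId)
  dose <- pool[seq(1, 2 * nPool, by = 2), , drop = FALSE] +
          pool[seq(2, 2 * nPool, by = 2), , drop = FALSE]
  refH <- .simHaplotypes(2L * config@nRef, maf, rBlock, lay$blockId)
  ref <- refH[seq(1, 2 * config@nRef, by = 2), , drop = FALSE] +
         refH[seq(2, 2 * config@nRef, by = 2), , drop = FALSE]
  i1 <- seq_len(config@n1)
  i2 <- c(seq_len(config@ns),
          config@n1 + seq_len(config@n2 - config@ns))
  study1 <- dose[i1, , drop = FALSE]
  study2 <- dose[i2, , drop = FALSE]
  colnames(study1) <- colnames(study2) <- colnames(ref) <- lay$snp
  list(study1 = study1, study2 = study2, ref = ref, maf = maf,
       layout = lay)
}

#' Draw bivariate polygenic effect sizes
#'
#' Per-SNP effects on the standardized-genotype scale: variances
#' \code{h2/m} for each trait; cross-trait covariance \code{rhoLocal/m_t}
#' inside the target block (local mode, 0 elsewhere) or \code{rhoGlobal/m}
#' genome-wide (global mode). Consumes 2m standard normals in a fixed
#' order, so draws under different covariance values with the same RNG
#' state are coupled (common random numbers).
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return list \code{beta}, \code{gamma}.
#' @export
drawEffects <- function(config) {
  m <- sum(config@blockSizes)
  lay <- .configLayout(config)
  s1 <- sqrt(config@h2[1] / m); s2 <- sqrt(config@h2[2] / m)
  cv <- rep(0, m)
  if (config@mode == "local") {
    tb <- lay$blockId == config@targetBlock
    cv[tb] <- config@rhoLocal / sum(tb)
  } else {
    cv[] <- config@rhoGlobal / m
  }
  if (any(cv^2 > s1^2 * s2^2 + 1e-15))
    stop("effect covariance matrix is not positive semidefinite")
  u <- rnorm(m); v <- rnorm(m)
  beta <- s1 * u
  b <- cv / s1                      # regression of gamma on u
  resid <- sqrt(pmax(s2^2 - b^2, 0))
  gamma <- b * u + resid * v
  list(beta = beta, gamma = gamma)
}

#' Simulate phenotypes with overlap-correlated noise
#'
#' \code{phi1 = X beta + eps}, \code{phi2 = Y gamma + delta}; noise
#' variances \code{1 - h2}; on the first \code{ns} (shared) samples the
#' noise pair is bivariate with covariance \code{rhoE}, independent
#' elsewhere. Phenotypes are divided by their empirical SD so the
#' unit-variance assumption of the z-score approximation holds exactly.
#'
#' @param X1,X2 column-standardized cohort genotype matrices.
#' @param beta,gamma effect vectors.
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return list \code{phi1}, \code{phi2}.
#' @export
simulatePhenotypes <- function(X1, X2, beta, gamma, config) {
  n1 <- nrow(X1); n2 <- nrow(X2); ns <- config@ns
  v1 <- 1 - config@h2[1]; v2 <- 1 - config@h2[2]
  eps <- rnorm(n1, sd = sqrt(v1))
  base <- rnorm(n2)
  delta <- sqrt(v2) * base
  if (ns > 0 && v1 > 0) {
    b <- config@rhoE / v1
    rv <- sqrt(max(v2 - b^2 * v1, 0))
    delta[seq_len(ns)] <- b * eps[seq_len(ns)] + rv * base[seq_len(ns)]
  }
  phi1 <- drop(X1 %*% beta) + eps
  phi2 <- drop(X2 %*% gamma) + delta
  list(phi1 = phi1 / sd(phi1), phi2 = phi2 / sd(phi2))
}

#' Marginal-association z scores
#'
#' \code{z_j = x_j' phi / sqrt(n)} for column-standardized genotypes and
#' a standardized phenotype: the score-test approximation used throughout
#' the model.
#'
#' @param X column-standardized genotype matrix.
#' @param phi phenotype vector (variance 1).
#' @return numeric z-score vector, one per SNP.
#' @export
runGwas <- function(X, phi) {
  drop(crossprod(X, phi)) / sqrt(nrow(X))
}

#' Simulate a complete study pair
#'
#' Runs the whole generative chain (genotypes, effects, phenotypes, z
#' scores) deterministically from the config seed and returns summary
#' statistics in the standard schema plus the true parameter record.
#' With \code{dir} set, writes the reference panel as a PLINK fileset,
#' both summary-statistics files, the partition and a truth JSON.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param dir optional output directory.
#' @return list \code{sumstats1}, \code{sumstats2} (data.frames SNP A1 A2
#'   Z N CHR BP), \code{panels}, \code{truth}, \code{layout}, and (when
#'   written) \code{paths}.
#' @export
simulateStudyPair <- function(config, dir = NULL) {
  panels <- simulateGenotypes(config)
  X1 <- standardizeGenotypes(panels$study1)
  X2 <- standardizeGenotypes(panels$study2)
  eff <- drawEffects(config)
  ph <- simulatePhenotypes(X1, X2, eff$beta, eff$gamma, config)
  z1 <- runGwas(X1, ph$phi1)
  z2 <- runGwas(X2, ph$phi2)
  lay <- panels$layout
  ss <- function(z, n) data.frame(SNP = lay$snp, A1 = "A", A2 = "G",
                                  Z = z, N = n, CHR = lay$chrom,
                                  BP = lay$pos, stringsAsFactors = FALSE)
  truth <- list(mode = config@mode, rhoLocal = config@rhoLocal,
                rhoGlobal = config@rhoGlobal, rhoE = config@rhoE,
                h2 = config@h2, n1 = config@n1, n2 = config@n2,
                ns = config@ns, seed = config@seed)
  out <- list(sumstats1 = ss(z1, config@n1), sumstats2 = ss(z2, config@n2),
              panels = panels, truth = truth, layout = lay)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pfx <- file.path(dir, "panel")
    writePlink(pfx, panels$ref, lay$bim)
    f1 <- file.path(dir, "sumstats1.txt")
    f2 <- file.path(dir, "sumstats2.txt")
    write.table(out$sumstats1, f1, quote = FALSE, sep = "\t",
                row.names = FALSE)
    write.table(out$sumstats2, f2, quote = FALSE, sep = "\t",
                row.names = FALSE)
    part <- file.path(dir, "partition.txt")
    pt <- data.frame(chr = paste0("chr",
                       as.character(GenomicRanges::seqnames(lay$partition))),
                     start = lay$partition$startBp,
                     stop = lay$partition$stopBp)
    write.table(pt, part, quote = FALSE, sep = "\t", row.names = FALSE)
    tf <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
    out$paths <- list(bfile = pfx, sumstats1 = f1, sumstats2 = f2,
                      partition = part, truth = tf)
  }
  out
}

#' Precompute the fixed part of a replicated simulation
#'
#' Genotype panels are held fixed across replicates (as when simulating
#' on real cohort genotypes); effects, noise and hence z scores are
#' redrawn per replicate. This caches the standardized cohort matrices,
#' the reference-panel eigen-systems per block and the LD scores.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return an opaque engine list consumed by
#'   \code{\link{replicateExperiment}}.
#' @export
simulationEngine <- function(config) {
  panels <- simulateGenotypes(config)
  lay <- panels$layout
  X1 <- standardizeGenotypes(panels$study1)
  X2 <- standardizeGenotypes(panels$study2)
  refStd <- standardizeGenotypes(panels$ref)
  if (length(attr(X1, "removed")) || length(attr(X2, "removed")) ||
      length(attr(refStd, "removed")))
    stop("simulationEngine: monomorphic SNPs in generated panels; ",
         "increase sample sizes or the MAF lower bound")
  nBlocks <- length(config@blockSizes)
  eigens <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    cols <- which(lay$blockId == b)
    eig <- eigenLD(estimateLD(refStd[, cols, drop = FALSE]),
                   nRef = config@nRef)
    r <- eig@rankCap
    eigens[[b]] <- list(idx = cols, w = eig@values[seq_len(r)],
                        U = eig@vectors[, seq_len(r), drop = FALSE],
                        m = length(cols))
  }
  scores <- computeLDScores(refStd, lay$pos, lay$chrom)
  list(config = config, X1 = X1, X2 = X2, eigens = eigens,
       ldScores = scores$ldScore, layout = lay)
}

## one replicate through the full estimator; assumes the ambient RNG
## state has been set by the caller
.engineReplicate <- function(engine, wantGlobal = FALSE, kMin = 10L,
                             nJackBlocks = NULL) {
  config <- engine$config
  eff <- drawEffects(config)
  ph <- simulatePhenotypes(engine$X1, engine$X2, eff$beta, eff$gamma,
                           config)
  z1 <- runGwas(engine$X1, ph$phi1)
  z2 <- runGwas(engine$X2, ph$phi2)
  lay <- engine$layout
  pair <- new("HarmonizedPair",
              snps = data.frame(snp = lay$snp, chrom = lay$chrom,
                                pos = lay$pos, z1 = z1, z2 = z2,
                                stringsAsFactors = FALSE),
              n1 = as.numeric(config@n1), n2 = as.numeric(config@n2),
              dropped = integer(0))
  scores <- data.frame(snp = lay$snp, ldScore = engine$ldScores,
                       stringsAsFactors = FALSE)
  if (is.null(nJackBlocks))
    nJackBlocks <- min(200L, max(2L, nrow(snpTable(pair)) %/% 3L))
  ic <- estimateIntercept(pair, scores, nBlocks = nJackBlocks)
  aHat <- ic@estimate; varA <- ic@variance
  n1 <- pair@n1; n2 <- pair@n2

  blocks <- engine$eigens
  fits <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    zt1 <- drop(crossprod(bl$U, z1[bl$idx]))
    zt2 <- drop(crossprod(bl$U, z2[bl$idx]))
    fits[[b]] <- selectK(zt1, zt2, bl$w, n1, n2, bl$m, aHat, varA,
                         kMin = kMin)
    if (!is.null(fits[[b]])) {
      fits[[b]]$p <- waldTest(fits[[b]]$rho, fits[[b]]$varTotal)
      fits[[b]]$w <- bl$w
      fits[[b]]$zt1 <- zt1
      fits[[b]]$zt2 <- zt2
      fits[[b]]$mi <- bl$m
    }
  }
  out <- list(fits = fits, intercept = ic,
              target = fits[[config@targetBlock]])
  if (wantGlobal) {
    ok <- !vapply(fits, is.null, logical(1))
    mTotal <- sum(vapply(fits[ok], `[[`, numeric(1), "mi"))
    g <- .pooledGlobalFit(fits[ok], n1, n2, mTotal, aHat, varA, kMin)
    if (!is.null(g))
      out$global <- list(rho = g$rho, varTotal = g$varTotal,
                         p = waldTest(g$rho, g$varTotal),
                         mTotal = mTotal, K = g$K)
  }
  out
}

#' Replicated simulation experiment
#'
#' Runs \code{nReps} independent replicates of the full pipeline
#' (effects, phenotypes, z scores, overlap intercept, adaptive-K local
#' estimation; pooled global estimation in global mode) on fixed panels
#' and summarizes calibration and accuracy against the configured truth.
#' Replicate r uses seed \code{(seed + 7919 * r) mod (2^31 - 1)}, so
#' replicates are reproducible in isolation and configs sharing a seed
#' use common random numbers.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param nReps number of replicates (>= 2; >= 50 for stable rates).
#' @param engine optional precomputed \code{\link{simulationEngine}}
#'   (must match \code{config} up to the covariance parameters).
#' @param alpha nominal test level for the rejection rate (default 0.05).
#' @param kMin adaptive-K lower bound.
#' @return list with \code{summary} (one-row data.frame: truth, nReps,
#'   mean, sd, bias, rmse, rejectRate, meanSE) and the per-replicate
#'   \code{estimates}, \code{pvalues}, \code{ses}.
#' @export
replicateExperiment <- function(config, nReps, engine = NULL,
                                alpha = 0.05, kMin = 10L) {
  if (nReps < 2) stop("need at least 2 replicates")
  if (is.null(engine)) {
    engine <- simulationEngine(config)
  } else {
    ec <- engine$config
    if (!identical(ec@blockSizes, config@blockSizes) ||
        ec@n1 != config@n1 || ec@n2 != config@n2 || ec@ns != config@ns ||
        ec@nRef != config@nRef || ec@seed != config@seed)
      stop("engine was built for an incompatible configuration")
    engine$config <- config  # covariance parameters may differ
  }
  wantGlobal <- config@mode == "global"
  truth <- if (wantGlobal) config@rhoGlobal else config@rhoLocal
  est <- pv <- se <- numeric(nReps)
  for (r in seq_len(nReps)) {
    set.seed((config@seed + 7919 * r) %% 2147483647)
    rep <- .engineReplicate(engine, wantGlobal = wantGlobal, kMin = kMin)
    src <- if (wantGlobal) rep$global else rep$target
    if (is.null(src)) { est[r] <- NA; pv[r] <- NA; se[r] <- NA; next }
    est[r] <- src$rho; pv[r] <- src$p
    se[r] <- sqrt(src$varTotal)
  }
  ok <- is.finite(est)
  summary <- data.frame(
    mode = config@mode, truth = truth, nReps = sum(ok),
    mean = mean(est[ok]), sd = sd(est[ok]),
    bias = mean(est[ok]) - truth,
    rmse = sqrt(mean((est[ok] - truth)^2)),
    rejectRate = mean(pv[ok] < alpha),
    meanSE = mean(se[ok]), stringsAsFactors = FALSE)
  list(summary = summary, estimates = est, pvalues = pv, ses = se)
}
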