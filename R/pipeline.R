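## End-to-end orchestration: the three entry points behind the
## command-line script (estimate, simulate, benchmark) plus the run
## manifest.

#' Full estimation pipeline from files
#'
#' Reads two summary-statistics files, a PLINK reference panel and an
#' LD-block partition; runs QC, harmonization, LD-score and overlap
#' intercept estimation, and per-block adaptive-K local covariance
#' estimation; writes the per-block results TSV and a JSON run manifest
#' (and, when requested, a one-line global summary TSV).
#'
#' @param sumstats1,sumstats2 summary-statistics file paths.
#' @param bfile PLINK fileset prefix for the reference panel.
#' @param partition partition file path.
#' @param out output prefix (writes \code{<out>.results.tsv},
#'   \code{<out>.manifest.json}, optionally \code{<out>.global.tsv}).
#' @param n1,n2 optional sample-size overrides (default: median N column).
#' @param global also compute the pooled genome-wide estimate.
#' @param mafMin,excludeMhc QC settings (see \code{\link{qcFilter}}).
#' @param kMin,kMax adaptive-K bounds.
#' @param nJackBlocks jackknife blocks for the intercept variance.
#' @param ldWindowBp LD-score window (default 1 Mb).
#' @param prevalence optional list for liability-scale output:
#'   \code{list(P1=, K1=, P2=, K2=)} sample/population prevalences; adds
#'   a \code{rho_liability} column.
#' @param seed seed echoed into the manifest (the pipeline itself is
#'   deterministic).
#' @return invisible list with \code{results}, \code{global},
#'   \code{intercept}, \code{manifest}.
#' @export
runEstimate <- function(sumstats1, sumstats2, bfile, partition, out,
                        n1 = NULL, n2 = NULL, global = FALSE,
                        mafMin = 0.05, excludeMhc = TRUE, kMin = 10L,
                        kMax = NULL, nJackBlocks = 200L, ldWindowBp = 1e6,
                        prevalence = NULL, seed = NA_integer_) {
  part <- readPartition(partition)
  panel <- readPlink(bfile)
  maf <- panelMaf(panel$genotypes)

  s1 <- readSumstats(sumstats1)
  s2 <- readSumstats(sumstats2)
  s1 <- qcFilter(annotateSnps(s1, panel$bim), maf, mafMin = mafMin,
                 excludeMhc = excludeMhc)
  s2 <- qcFilter(annotateSnps(s2, panel$bim), maf, mafMin = mafMin,
                 excludeMhc = excludeMhc)
  pair <- harmonizePair(s1, s2, panel$bim)
  if (!is.null(n1)) pair@n1 <- n1
  if (!is.null(n2)) pair@n2 <- n2

  tab <- snpTable(pair)
  pcols <- match(tab$snp, panel$bim$snp)
  refStd <- standardizeGenotypes(panel$genotypes[, pcols, drop = FALSE])
  scores <- computeLDScores(refStd, tab$pos, tab$chrom,
                            windowBp = ldWindowBp)
  scores$snp <- tab$snp
  ic <- estimateIntercept(pair, scores, nBlocks = nJackBlocks)

  results <- estimateLocalBlocks(pair, panel$genotypes, part, ic,
                                 kMin = kMin, kMax = kMax)
  if (!is.null(prevalence)) {
    cc <- liabilityConstant(prevalence$P1, prevalence$K1,
                            prevalence$P2, prevalence$K2)
    results$rho_liability <- results$rho / cc
  }
  writeResults(results, paste0(out, ".results.tsv"))

  glob <- NULL
  if (global) {
    glob <- globalCovariance(results, pair, ic)
    sl <- sumLocalVsGlobal(results$rho, glob$rho)
    gl <- data.frame(rho_global = sprintf("%.6e", glob$rho),
                     var = sprintf("%.6e", glob$var),
                     p = sprintf("%.6e", glob$p),
                     sum_local = sprintf("%.6e", sl$sums),
                     delta = sprintf("%.6e", sl$deltas))
    write.table(gl, paste0(out, ".global.tsv"), quote = FALSE,
                sep = "\t", row.names = FALSE)
  }

  manifest <- list(
    inputs = list(sumstats1 = sumstats1, sumstats2 = sumstats2,
                  bfile = bfile, partition = partition),
    n1 = pair@n1, n2 = pair@n2, mSnps = nSnps(pair),
    qc = list(study1 = as.list(attr(s1, "dropped")),
              study2 = as.list(attr(s2, "dropped")),
              allele_mismatch = unname(pair@dropped),
              unassigned = attr(results, "unassigned")),
    intercept = list(a_hat = ic@estimate, var_a = ic@variance,
                     slope = ic@slope, n_jackknife = ic@nBlocks),
    blocks = lapply(seq_len(nrow(results)), function(b)
      list(chrom = results$chrom[b], start = results$start[b],
           stop = results$stop[b], status = results$status[b])),
    settings = list(mafMin = mafMin, excludeMhc = excludeMhc,
                    kMin = kMin, kMax = kMax,
                    nJackBlocks = nJackBlocks, ldWindowBp = ldWindowBp),
    version = as.character(packageVersion("localgcov")),
    seed = seed)
  jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, global = glob, intercept = ic,
                 manifest = manifest))
}

#' Write a simulated study pair to disk
#'
#' Thin wrapper over \code{\link{simulateStudyPair}} for the
#' command-line interface: builds a config from scenario parameters and
#' writes panel, summary statistics, partition and truth record.
#'
#' @param dir output directory.
#' @param ... passed to \code{\link{simConfig}} (must include
#'   \code{seed}).
#' @return invisible list of output paths.
#' @export
runSimulate <- function(dir, ...) {
  config <- simConfig(...)
  res <- simulateStudyPair(config, dir = dir)
  invisible(res$paths)
}

#' Benchmark the estimator over a parameter grid
#'
#' Runs \code{\link{replicateExperiment}} for each covariance value in
#' \code{rhoGrid} (reusing one panel engine) and returns the stacked
#' evaluation table: rejection proportion at \code{alpha}, mean estimate,
#' bias, RMSE and mean reported SE versus the empirical SD.
#'
#' @param rhoGrid numeric vector of true covariance values.
#' @param nReps replicates per grid point.
#' @param mode \code{"local"} or \code{"global"}.
#' @param alpha nominal level (default 0.05).
#' @param out optional TSV path for the table.
#' @param ... further arguments to \code{\link{simConfig}} (must include
#'   \code{seed}).
#' @return data.frame, one row per grid point.
#' @export
runBenchmark <- function(rhoGrid, nReps, mode = "local", alpha = 0.05,
                         out = NULL, ...) {
  base <- if (mode == "local") simConfig(mode = mode, rhoLocal = 0, ...)
          else simConfig(mode = mode, rhoGlobal = 0, ...)
  engine <- simulationEngine(base)
  rows <- lapply(rhoGrid, function(r) {
    cfg <- base
    if (mode == "local") cfg@rhoLocal <- r else cfg@rhoGlobal <- r
    validObject(cfg)
    replicateExperiment(cfg, nReps, engine = engine,
                        alpha = alpha)$summary
  })
  tabl <- do.call(rbind, rows)
  if (!is.null(out))
    write.table(tabl, out, quote = FALSE, sep = "\t", row.names = FALSE)
  tabl
}
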