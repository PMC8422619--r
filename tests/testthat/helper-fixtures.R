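## shared fixtures: tiny in-memory panels, summary-stat writers, and a
## cache so expensive simulation engines are built once per session

.cache <- new.env(parent = emptyenv())

cachedEngine <- function(key, config) {
  if (is.null(.cache[[key]])) .cache[[key]] <- simulationEngine(config)
  .cache[[key]]
}

cachedRun <- function(key, fun) {
  if (is.null(.cache[[key]])) .cache[[key]] <- fun()
  .cache[[key]]
}

writeSumstatsFile <- function(df, path = tempfile(fileext = ".txt")) {
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  path
}

## random dosage panel with named SNPs on one chromosome
tinyPanel <- function(n = 50, m = 8, seed = 1, chrom = 1L) {
  set.seed(seed)
  geno <- matrix(rbinom(n * m, 2L, 0.4), n, m)
  colnames(geno) <- sprintf("rs%03d", seq_len(m))
  bim <- data.frame(chrom = chrom, snp = colnames(geno), cm = 0,
                    pos = seq_len(m) * 1000L, a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  list(geno = geno, bim = bim)
}

makePair <- function(snp, chrom, pos, z1, z2, n1 = 1000, n2 = 1000) {
  new("HarmonizedPair",
      snps = data.frame(snp = snp, chrom = chrom, pos = pos,
                        z1 = z1, z2 = z2, stringsAsFactors = FALSE),
      n1 = n1, n2 = n2, dropped = integer(0))
}

## geometry used by the grid-recovery checks: 2400 SNPs in 50 blocks,
## target block first
recoveryBlocks <- rep(48L, 50L)
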