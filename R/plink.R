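## Minimal PLINK 1 bed/bim/fam reader and writer (SNP-major, 2 bits per
## genotype). Dosages count copies of the bim A1 allele: byte codes
## 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing (NA).

.bedLookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      dec <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
      m <- matrix(NA_real_, 256, 4)
      for (b in 0:255) {
        v <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
        m[b + 1, ] <- dec[as.character(v)]
      }
      tab <<- m
    }
    tab
  }
})

#' Read a PLINK 1 binary genotype fileset
#'
#' @param prefix path prefix of the \code{.bed/.bim/.fam} triplet.
#' @return list with \code{genotypes} (samples x SNPs numeric matrix of A1
#'   dosages in \{0,1,2,NA\}), \code{bim} (data.frame \code{chrom},
#'   \code{snp}, \code{cm}, \code{pos}, \code{a1}, \code{a2}) and
#'   \code{fam} (6-column data.frame).
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bimf <- paste0(prefix, ".bim")
  famf <- paste0(prefix, ".fam")
  for (f in c(bed, bimf, famf))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  bim <- read.table(bimf, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp", "cm", "pos", "a1", "a2"))
  fam <- read.table(famf, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = 3 + m * bytesPerSnp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  body <- as.integer(raw[-(1:3)])
  lut <- .bedLookup()
  ## decode all bytes at once: (m*bytesPerSnp) x 4, then trim per SNP
  dec <- lut[body + 1L, , drop = FALSE]
  geno <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    rows <- ((j - 1) * bytesPerSnp + 1):(j * bytesPerSnp)
    vals <- t(dec[rows, , drop = FALSE])  # 4 x bytesPerSnp, sample-order
    geno[, j] <- as.vector(vals)[seq_len(n)]
  }
  colnames(geno) <- bim$snp
  list(genotypes = geno, bim = bim, fam = fam)
}

#' Write a PLINK 1 binary genotype fileset
#'
#' @param prefix output path prefix.
#' @param genotypes samples x SNPs matrix of A1-allele dosages
#'   (0/1/2/NA).
#' @param bim data.frame with columns \code{chrom}, \code{snp}, \code{cm},
#'   \code{pos}, \code{a1}, \code{a2}.
#' @param fam optional 6-column data.frame; a default one is generated.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(prefix, genotypes, bim, fam = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(nrow(bim) == m)
  if (is.null(fam))
    fam <- data.frame(fid = paste0("F", seq_len(n)),
                      iid = paste0("I", seq_len(n)),
                      pat = 0, mat = 0, sex = 0, pheno = -9)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  enc <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # dosage -> 2-bit code; NA -> 1
  bytesPerSnp <- ceiling(n / 4)
  pad <- bytesPerSnp * 4 - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  shift <- c(1L, 4L, 16L, 64L)  # 2-bit positions within a byte
  out <- raw(m * bytesPerSnp)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    code <- ifelse(is.na(g), 1L, enc[as.character(g)])
    if (pad > 0) code <- c(code, rep(3L, pad))  # pad with hom-A2 (0)
    cm <- matrix(code, nrow = 4)
    bytes <- as.integer(colSums(cm * shift))
    out[((j - 1) * bytesPerSnp + 1):(j * bytesPerSnp)] <- as.raw(bytes)
  }
  writeBin(out, con)
  invisible(prefix)
}

#' Reference-panel minor allele frequencies
#'
#' @param genotypes samples x SNPs dosage matrix (A1 counts, NA allowed).
#' @return named vector of per-SNP minor allele frequencies
#'   \code{min(f, 1-f)} where f is the A1 allele frequency.
#' @export
panelMaf <- function(genotypes) {
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  setNames(pmin(f, 1 - f), colnames(genotypes))
}
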