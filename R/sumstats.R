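## Reading, QC and harmonization of GWAS summary statistics against a
## reference panel and a genome partition of approximately independent
## LD blocks.

.VALID_ALLELES <- c("A", "C", "G", "T")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.isAmbiguous <- function(a1, a2) a2 == unname(.complement[a1])

#' Read a GWAS summary-statistics file
#'
#' Parses a whitespace/tab-delimited summary-statistics file in the munged
#' convention: columns \code{SNP}, \code{A1} (effect allele), \code{A2}
#' (other allele), \code{Z}, \code{N} (case-insensitive; \code{CHR} and
#' \code{BP} are picked up when present). Gzip-compressed files are read
#' transparently. Rows with missing or non-finite z scores, non-SNV allele
#' codes (anything outside A/C/G/T, e.g. indel codes), or equal alleles are
#' dropped with a message; duplicated SNP ids keep the first occurrence.
#'
#' @param path path to the file.
#' @return data.frame with columns \code{snp}, \code{a1}, \code{a2},
#'   \code{z}, \code{n} (and \code{chrom}, \code{pos} when present), plus a
#'   \code{"dropped"} attribute with per-reason counts. The study sample
#'   size is taken as a single scalar (\code{attr(x, "n")}): the median of
#'   the N column, with a message if N varies across SNPs.
#' @export
readSumstats <- function(path) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  df <- tryCatch(read.table(path, header = TRUE, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot read ", path, ": ",
                                          conditionMessage(e)))
  nm <- toupper(names(df))
  need <- c("SNP", "A1", "A2", "Z", "N")
  miss <- setdiff(need, nm)
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  col <- function(x) df[[which(nm == x)[1]]]
  out <- data.frame(snp = as.character(col("SNP")),
                    a1 = toupper(as.character(col("A1"))),
                    a2 = toupper(as.character(col("A2"))),
                    z = suppressWarnings(as.numeric(col("Z"))),
                    n = suppressWarnings(as.numeric(col("N"))),
                    stringsAsFactors = FALSE)
  if ("CHR" %in% nm) out$chrom <- suppressWarnings(as.integer(col("CHR")))
  if ("BP" %in% nm) out$pos <- suppressWarnings(as.integer(col("BP")))

  dropped <- c(nonfinite_z = 0L, non_snv = 0L, duplicate = 0L)
  keep <- is.finite(out$z)
  dropped["nonfinite_z"] <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  ok <- out$a1 %in% .VALID_ALLELES & out$a2 %in% .VALID_ALLELES &
    out$a1 != out$a2
  dropped["non_snv"] <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  dup <- duplicated(out$snp)
  dropped["duplicate"] <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  if (any(dropped > 0))
    message("readSumstats: dropped ",
            paste(names(dropped)[dropped > 0], dropped[dropped > 0],
                  sep = "=", collapse = ", "))
  nScalar <- if (nrow(out)) median(out$n, na.rm = TRUE) else NA_real_
  if (nrow(out) && length(unique(out$n[is.finite(out$n)])) > 1L)
    message("readSumstats: per-SNP N varies (range ",
            paste(range(out$n, na.rm = TRUE), collapse = "-"),
            "); using median ", nScalar)
  attr(out, "n") <- nScalar
  attr(out, "dropped") <- dropped
  rownames(out) <- NULL
  out
}

#' Annotate summary statistics with reference-panel positions
#'
#' Attaches chromosome and base-pair position from a PLINK .bim table and
#' restricts to SNPs present in the panel (the panel intersection step of
#' harmonization).
#'
#' @param stats data.frame from \code{\link{readSumstats}}.
#' @param bim data.frame with columns \code{chrom}, \code{snp}, \code{pos},
#'   \code{a1}, \code{a2} (as returned in \code{readPlink()$bim}).
#' @return \code{stats} restricted to panel SNPs with columns \code{chrom}
#'   and \code{pos} replaced by the panel's coordinates.
#' @export
annotateSnps <- function(stats, bim) {
  idx <- match(stats$snp, bim$snp)
  keep <- !is.na(idx)
  out <- stats[keep, , drop = FALSE]
  out$chrom <- bim$chrom[idx[keep]]
  out$pos <- bim$pos[idx[keep]]
  attr(out, "n") <- attr(stats, "n", exact = TRUE)
  attr(out, "dropped") <- c(attr(stats, "dropped", exact = TRUE),
                            not_in_panel = sum(!keep))
  rownames(out) <- NULL
  out
}

#' Quality-control filter for summary statistics
#'
#' Retains autosomal SNPs (chromosomes 1-22) with reference-panel minor
#' allele frequency at least \code{mafMin}, removes strand-ambiguous SNPs
#' (allele pairs A/T or C/G, whose orientation cannot be resolved between
#' studies), and optionally excludes the MHC region.
#'
#' @param stats annotated summary statistics (needs \code{chrom},
#'   \code{pos}).
#' @param maf named numeric vector of reference-panel MAFs by SNP id.
#' @param mafMin minimum MAF (default 0.05).
#' @param excludeMhc drop SNPs in the MHC window (default TRUE).
#' @param mhc \code{c(chrom, start, stop)} half-open MHC window; the
#'   default chr6:25-35 Mb is the usual hg19 convention.
#' @return filtered data.frame with updated \code{"dropped"} attribute.
#' @export
qcFilter <- function(stats, maf, mafMin = 0.05, excludeMhc = TRUE,
                     mhc = c(6, 25e6, 35e6)) {
  d <- integer(0)
  auto <- !is.na(stats$chrom) & stats$chrom >= 1L & stats$chrom <= 22L
  d["non_autosomal"] <- sum(!auto)
  out <- stats[auto, , drop = FALSE]
  snpMaf <- unname(maf[out$snp])
  okMaf <- !is.na(snpMaf) & snpMaf >= mafMin
  d["low_maf"] <- sum(!okMaf)
  out <- out[okMaf, , drop = FALSE]
  amb <- .isAmbiguous(out$a1, out$a2)
  d["strand_ambiguous"] <- sum(amb)
  out <- out[!amb, , drop = FALSE]
  if (excludeMhc) {
    inMhc <- out$chrom == mhc[1] & out$pos >= mhc[2] & out$pos < mhc[3]
    d["mhc"] <- sum(inMhc)
    out <- out[!inMhc, , drop = FALSE]
  }
  if (!nrow(out)) message("qcFilter: no SNPs retained")
  attr(out, "n") <- attr(stats, "n", exact = TRUE)
  attr(out, "dropped") <- c(attr(stats, "dropped", exact = TRUE), d)
  rownames(out) <- NULL
  out
}

#' Harmonize two summary-statistics sets against a reference panel
#'
#' Intersects the two studies and the panel on SNP id, aligns study 1's z
#' scores to the panel's allele coding (sign-flipped where study 1's effect
#' allele is the panel's other allele) and study 2's to study 1's. SNPs
#' whose allele pair matches neither orientation in either comparison are
#' dropped and counted.
#'
#' @param s1,s2 QC'd summary statistics (from \code{\link{qcFilter}}).
#' @param bim panel SNP table (\code{chrom}, \code{snp}, \code{pos},
#'   \code{a1}, \code{a2}).
#' @return a \code{\linkS4class{HarmonizedPair}}, SNPs ordered by
#'   chromosome and position.
#' @export
harmonizePair <- function(s1, s2, bim) {
  common <- intersect(intersect(s1$snp, s2$snp), bim$snp)
  if (!length(common))
    stop("harmonizePair: empty SNP intersection (study1 has ", nrow(s1),
         ", study2 has ", nrow(s2), ", panel has ", nrow(bim), " SNPs)")
  i1 <- match(common, s1$snp); i2 <- match(common, s2$snp)
  ip <- match(common, bim$snp)
  a1p <- toupper(bim$a1[ip]); a2p <- toupper(bim$a2[ip])

  orient <- function(aEff, aOth, refEff, refOth) {
    same <- aEff == refEff & aOth == refOth
    swap <- aEff == refOth & aOth == refEff
    ifelse(same, 1, ifelse(swap, -1, NA_real_))
  }
  f1 <- orient(s1$a1[i1], s1$a2[i1], a1p, a2p)
  ## study 2 matched against study 1's (panel-aligned) orientation
  f2raw <- orient(s2$a1[i2], s2$a2[i2], s1$a1[i1], s1$a2[i1])
  keep <- !is.na(f1) & !is.na(f2raw)
  nMismatch <- sum(!keep)
  if (!any(keep))
    stop("harmonizePair: no SNPs with consistent allele pairs")
  snps <- data.frame(snp = common[keep],
                     chrom = bim$chrom[ip[keep]],
                     pos = bim$pos[ip[keep]],
                     z1 = s1$z[i1[keep]] * f1[keep],
                     z2 = s2$z[i2[keep]] * f2raw[keep] * f1[keep],
                     stringsAsFactors = FALSE)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  n1 <- attr(s1, "n", exact = TRUE); n2 <- attr(s2, "n", exact = TRUE)
  if (is.null(n1) || !is.finite(n1)) n1 <- median(s1$n, na.rm = TRUE)
  if (is.null(n2) || !is.finite(n2)) n2 <- median(s2$n, na.rm = TRUE)
  if (nMismatch > 0)
    message("harmonizePair: dropped ", nMismatch,
            " SNPs with unmatched allele pairs")
  new("HarmonizedPair", snps = snps, n1 = n1, n2 = n2,
      dropped = c(allele_mismatch = nMismatch))
}

#' Read a genome partition of approximately independent LD blocks
#'
#' Parses a 3-column whitespace-delimited file (header \code{chr start
#' stop}; chromosome tokens like \code{chr1} or \code{1}) into a sorted
#' \code{GRanges}. Intervals are half-open \code{[start, stop)} on the
#' base-pair scale; they are stored as 1-based closed ranges
#' \code{[start, stop-1]} so overlap queries respect that convention, with
#' the original bounds kept in metadata columns \code{startBp}/\code{stopBp}.
#'
#' @param path partition file path.
#' @return \code{GRanges} sorted by chromosome and start.
#' @export
readPartition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("partition file needs 3 columns: chr start stop")
  names(df)[1:3] <- c("chr", "start", "stop")
  chrom <- as.integer(sub("^chr", "", as.character(df$chr)))
  start <- as.numeric(df$start); stop_ <- as.numeric(df$stop)
  if (any(is.na(chrom))) stop("unparseable chromosome token in partition")
  if (any(stop_ <= start)) {
    bad <- which(stop_ <= start)[1]
    stop("partition block with stop <= start at line ", bad, ": ",
         df$chr[bad], " ", df$start[bad], " ", df$stop[bad])
  }
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; stop_ <- stop_[o]
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = stop_ - 1),
    startBp = start, stopBp = stop_)
  ## non-overlap within chromosome (half-open, so touching blocks are fine)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) > 1) {
      ov <- which(start[i][-1] < stop_[i][-length(i)])
      if (length(ov))
        stop("overlapping partition blocks on chromosome ", ch, ": (",
             start[i][ov[1]], ",", stop_[i][ov[1]], ") and (",
             start[i][ov[1] + 1], ",", stop_[i][ov[1] + 1], ")")
    }
  }
  gr
}

#' Assign harmonized SNPs to partition blocks
#'
#' A SNP at position p on chromosome c belongs to block (c, start, stop)
#' iff start <= p < stop. SNPs covered by no block are dropped and counted.
#'
#' @param pair a \code{HarmonizedPair}.
#' @param partition \code{GRanges} from \code{\link{readPartition}}.
#' @return list of integer vectors (row indices into \code{snpTable(pair)}),
#'   one per block, with attribute \code{"unassigned"} (count of SNPs in no
#'   block).
#' @export
assignToBlocks <- function(pair, partition) {
  tab <- pair@snps
  snpGr <- GenomicRanges::GRanges(seqnames = tab$chrom,
                                  ranges = IRanges::IRanges(tab$pos, tab$pos))
  hits <- GenomicRanges::findOverlaps(snpGr, partition)
  idx <- vector("list", length(partition))
  sp <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  for (k in names(sp)) idx[[as.integer(k)]] <- sort(unname(sp[[k]]))
  idx[vapply(idx, is.null, logical(1))] <- list(integer(0))
  assigned <- length(unique(S4Vectors::queryHits(hits)))
  attr(idx, "unassigned") <- nrow(tab) - assigned
  idx
}
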