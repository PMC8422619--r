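## Reference-panel LD: genotype standardization, block LD matrices and
## their eigen-systems, z-score decorrelation, and LD scores.

#' Standardize a genotype dosage matrix
#'
#' Missing entries are mean-imputed per SNP, then each column is centered
#' and scaled to mean 0 and variance 1 (variance with divisor n, so that
#' the LD matrix \code{crossprod(X)/n} has a unit diagonal exactly).
#' Monomorphic (zero-variance) columns are removed with a message.
#'
#' @param genotypes samples x SNPs dosage matrix (0/1/2/NA).
#' @return standardized matrix; removed column indices in attribute
#'   \code{"removed"}.
#' @export
standardizeGenotypes <- function(genotypes) {
  X <- as.matrix(genotypes)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  mu <- colMeans(X)
  X <- sweep(X, 2, mu, "-")
  s <- sqrt(colMeans(X^2))
  bad <- unname(which(s < 1e-12 | !is.finite(s)))
  if (length(bad)) {
    message("standardizeGenotypes: removed ", length(bad),
            " zero-variance column(s)")
    X <- X[, -bad, drop = FALSE]
    s <- s[-bad]
  }
  if (!ncol(X)) {
    warning("standardizeGenotypes: no usable SNPs in block")
    attr(X, "removed") <- bad
    return(X)
  }
  X <- sweep(X, 2, s, "/")
  attr(X, "removed") <- bad
  X
}

#' Estimate a block LD matrix
#'
#' \code{V = crossprod(X)/n} on a column-standardized panel, so the
#' diagonal is exactly 1 and \code{trace(V)} equals the SNP count.
#'
#' @param block standardized genotype matrix (from
#'   \code{\link{standardizeGenotypes}}).
#' @return symmetric LD matrix.
#' @export
estimateLD <- function(block) {
  n <- nrow(block)
  if (n < 2) stop("estimateLD: need at least 2 reference samples")
  crossprod(block) / n
}

#' Eigen-decompose a block LD matrix
#'
#' Eigenvalues are clipped at zero from below and sorted in decreasing
#' order with matching eigenvectors. The usable rank is capped at
#' \code{min(m, nRef)} and at the numerical rank (eigenvalues below
#' \code{1e-8 * max(w)} count as zero).
#'
#' @param V symmetric LD matrix.
#' @param nRef reference-panel sample size used to estimate \code{V}
#'   (caps the usable rank); default \code{Inf} (no cap beyond m).
#' @return an \code{\linkS4class{LDBlockEigen}}.
#' @export
eigenLD <- function(V, nRef = Inf) {
  if (max(abs(V - t(V))) > 1e-8) stop("eigenLD: matrix is not symmetric")
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  w <- pmax(e$values, 0)
  numRank <- sum(w > 1e-8 * max(w, 1e-300))
  m <- ncol(V)
  new("LDBlockEigen", values = w, vectors = e$vectors, m = as.integer(m),
      rankCap = as.integer(min(m, nRef, numRank)))
}

#' Decorrelate a block z-score vector
#'
#' Rotates z scores into the eigenbasis of the block LD matrix,
#' \eqn{\tilde z = U^T z}. The rotation is an isometry:
#' \code{sum(zt^2) == sum(z^2)}.
#'
#' @param z z scores of the block's SNPs (panel allele coding).
#' @param eig the block's \code{LDBlockEigen}.
#' @return numeric vector of decorrelated scores, one per eigen-component.
#' @export
transformZ <- function(z, eig) {
  if (length(z) != nrow(eig@vectors))
    stop("transformZ: z has length ", length(z), " but block has ",
         nrow(eig@vectors), " SNPs")
  drop(crossprod(eig@vectors, z))
}

#' LD scores within a physical window
#'
#' For each SNP j, \code{sum over k with |pos_k - pos_j| <= window of
#' r2_adj(j,k)}, using the unbiased small-sample adjustment
#' \code{r2_adj = r2 - (1 - r2)/(n - 2)}. Computed per chromosome;
#' stretches separated by more than the window are processed
#' independently.
#'
#' @param panel standardized genotype matrix (all SNPs of one or more
#'   chromosomes).
#' @param pos base-pair positions (same order as panel columns).
#' @param chrom chromosome per SNP (same order); scalar is recycled.
#' @param windowBp physical window, default 1 Mb.
#' @return data.frame \code{snp}, \code{ldScore}.
#' @export
computeLDScores <- function(panel, pos, chrom = 1L, windowBp = 1e6) {
  m <- ncol(panel); n <- nrow(panel)
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  score <- numeric(m)
  adjust <- function(r2) r2 - (1 - r2) / (n - 2)
  for (ch in unique(chrom)) {
    ci <- which(chrom == ch)
    o <- ci[order(pos[ci])]
    p <- pos[o]
    ## split into chunks whose gaps exceed the window (no cross terms)
    breaks <- c(0L, which(diff(p) > windowBp), length(o))
    for (b in seq_len(length(breaks) - 1L)) {
      ix <- o[(breaks[b] + 1L):breaks[b + 1L]]
      X <- panel[, ix, drop = FALSE]
      R2 <- (crossprod(X) / n)^2
      inWin <- abs(outer(pos[ix], pos[ix], "-")) <= windowBp
      A <- adjust(R2) * inWin
      score[ix] <- rowSums(A)
    }
  }
  data.frame(snp = colnames(panel) %||% as.character(seq_len(m)),
             ldScore = score, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
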