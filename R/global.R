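## Genome-wide genetic covariance as the block-diagonal special case of
## the local estimator: all blocks' decorrelated components enter one
## pooled no-intercept WLS, with a single adaptively selected K over the
## eigenvalue-sorted pooled spectrum.

#' Pooled genome-wide genetic covariance
#'
#' Treats the whole genome as a single region whose LD matrix is block
#' diagonal: every block's decorrelated components are pooled, sorted by
#' eigenvalue (each block already capped at its usable rank), and a
#' single adaptive K is selected with the same variance criterion as in
#' local estimation.
#' The per-SNP effect covariance is \code{rho/mTotal}, so heritabilities
#' and the slope are on the total-SNP-count scale.
#'
#' @param localResults output of \code{\link{estimateLocalBlocks}} (its
#'   \code{"internals"} attribute is used).
#' @param pair the \code{\linkS4class{HarmonizedPair}}.
#' @param intercept the \code{\linkS4class{CrossTraitIntercept}} used for
#'   the local fits.
#' @param kMin lower bound of the pooled K grid (default 10).
#' @return list \code{rho}, \code{var}, \code{p}, \code{corr}, \code{h2_1},
#'   \code{h2_2}, \code{mTotal}, \code{K}.
#' @export
globalCovariance <- function(localResults, pair, intercept, kMin = 10L) {
  internals <- attr(localResults, "internals")
  blocks <- Filter(Negate(is.null), internals)
  if (!length(blocks)) stop("globalCovariance: no estimable blocks")
  n1 <- pair@n1; n2 <- pair@n2
  mTotal <- sum(vapply(blocks, `[[`, numeric(1), "mi"))
  fit <- .pooledGlobalFit(blocks, n1, n2, mTotal,
                          intercept@estimate, intercept@variance, kMin)
  if (is.null(fit)) stop("globalCovariance: degenerate pooled spectrum")
  corr <- if (fit$h21 > 0 && fit$h22 > 0)
    fit$rho / sqrt(fit$h21 * fit$h22) else NA_real_
  list(rho = fit$rho, var = fit$varTotal,
       p = waldTest(fit$rho, fit$varTotal), corr = corr,
       h2_1 = fit$h21, h2_2 = fit$h22, mTotal = mTotal, K = fit$K)
}

## pool full-rank decorrelated components of all blocks, sort by
## eigenvalue, cap at the reference sample size, one adaptive K
.pooledGlobalFit <- function(blocks, n1, n2, mTotal, aHat, varA,
                             kMin = 10L) {
  w <- unlist(lapply(blocks, `[[`, "w"))
  zt1 <- unlist(lapply(blocks, `[[`, "zt1"))
  zt2 <- unlist(lapply(blocks, `[[`, "zt2"))
  ## components are already rank-capped per block (each block's LD has
  ## rank <= nRef); the pooled block-diagonal spectrum keeps them all
  o <- order(w, decreasing = TRUE)
  selectK(zt1[o], zt2[o], w[o], n1, n2, mTotal, aHat, varA, kMin = kMin)
}

#' Concordance of summed local estimates with the global estimate
#'
#' For one trait pair: the sum of per-block local covariances and its
#' difference from the global estimate. Across several trait pairs (or
#' replicates): additionally the squared correlation between the sums and
#' the global estimates.
#'
#' @param localRho numeric vector of per-block local estimates for one
#'   pair, or a list of such vectors for several pairs.
#' @param globalRho the matching global estimate(s).
#' @return list \code{sums}, \code{globals}, \code{deltas}, \code{r2}
#'   (NA when fewer than 2 pairs).
#' @export
sumLocalVsGlobal <- function(localRho, globalRho) {
  if (!is.list(localRho)) localRho <- list(localRho)
  sums <- vapply(localRho, function(x) sum(x, na.rm = TRUE), numeric(1))
  stopifnot(length(sums) == length(globalRho))
  deltas <- sums - globalRho
  r2 <- if (length(sums) >= 2) cor(sums, globalRho)^2 else NA_real_
  list(sums = sums, globals = globalRho, deltas = deltas, r2 = r2)
}
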