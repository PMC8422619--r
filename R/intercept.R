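## Cross-trait LD score regression: the intercept estimates the
## sample-overlap nuisance term a = n_s * rho_t / sqrt(n1 * n2), where
## rho_t is the total (genetic + non-genetic) covariance of the
## overlapping samples' phenotypes. Robustness to unknown overlap comes
## from never constraining this intercept.

## weighted intercept/slope from sufficient sums; wgt are regression weights
.wlsLine <- function(Su, Sux, Suxx, Suy, Suxy) {
  det <- Su * Suxx - Sux^2
  if (abs(det) < 1e-12 * max(Su * Suxx, 1))
    stop("degenerate design: LD scores are (nearly) constant; ",
         "use a fixed intercept instead")
  a <- (Suxx * Suy - Sux * Suxy) / det
  b <- (Su * Suxy - Sux * Suy) / det
  c(intercept = a, slope = b)
}

#' Cross-trait LD score regression
#'
#' Weighted regression of the per-SNP z-score products \code{z1*z2} on
#' \code{sqrt(n1*n2) * ldScore / m} with a free intercept. The fitted
#' intercept estimates the overlap term \eqn{n_s\rho_t/\sqrt{n_1 n_2}};
#' the slope is a genome-wide covariance estimate (by-product). Weights
#' default to \code{1/max(ldScore, 1)} as a heteroskedasticity proxy.
#'
#' @param pair a \code{\linkS4class{HarmonizedPair}} (genome-wide SNP set).
#' @param scores data.frame \code{snp}, \code{ldScore} from
#'   \code{\link{computeLDScores}}.
#' @param weighted use the reciprocal-LD-score weights (default TRUE).
#' @return named vector \code{intercept}, \code{slope}.
#' @export
crossTraitRegression <- function(pair, scores, weighted = TRUE) {
  tab <- snpTable(pair)
  if (nrow(tab) < 200)
    warning("cross-trait regression on fewer than 200 SNPs is unreliable")
  ell <- scores$ldScore[match(tab$snp, scores$snp)]
  if (anyNA(ell)) stop("missing LD scores for some harmonized SNPs")
  m <- nrow(tab)
  x <- sqrt(pair@n1 * pair@n2) * ell / m
  y <- tab$z1 * tab$z2
  u <- if (weighted) 1 / pmax(ell, 1) else rep(1, m)
  .wlsLine(sum(u), sum(u * x), sum(u * x^2), sum(u * y), sum(u * x * y))
}

#' Block-jackknife variance of the cross-trait intercept
#'
#' Delete-one-block jackknife over contiguous genome-ordered SNP blocks:
#' the intercept is refit with each block removed and the variance is
#' \code{(B-1)/B * sum((a_b - mean(a_b))^2)}.
#'
#' @inheritParams crossTraitRegression
#' @param nBlocks number of contiguous jackknife blocks (default 200).
#' @return variance of the intercept estimate.
#' @export
jackknifeVariance <- function(pair, scores, nBlocks = 200, weighted = TRUE) {
  tab <- snpTable(pair)
  m <- nrow(tab)
  if (nBlocks < 2) stop("need at least 2 jackknife blocks")
  if (m < nBlocks)
    stop("fewer SNPs (", m, ") than jackknife blocks (", nBlocks, ")")
  ell <- scores$ldScore[match(tab$snp, scores$snp)]
  x <- sqrt(pair@n1 * pair@n2) * ell / m
  y <- tab$z1 * tab$z2
  u <- if (weighted) 1 / pmax(ell, 1) else rep(1, m)
  grp <- ceiling(seq_len(m) / (m / nBlocks))
  gs <- function(v) as.numeric(rowsum(v, grp))
  Su <- sum(u); Sux <- sum(u * x); Suxx <- sum(u * x^2)
  Suy <- sum(u * y); Suxy <- sum(u * x * y)
  gU <- gs(u); gUx <- gs(u * x); gUxx <- gs(u * x^2)
  gUy <- gs(u * y); gUxy <- gs(u * x * y)
  B <- length(gU)
  aDel <- numeric(B)
  for (b in seq_len(B))
    aDel[b] <- .wlsLine(Su - gU[b], Sux - gUx[b], Suxx - gUxx[b],
                        Suy - gUy[b], Suxy - gUxy[b])[["intercept"]]
  (B - 1) / B * sum((aDel - mean(aDel))^2)
}

#' Estimate the sample-overlap intercept with its variance
#'
#' Convenience wrapper running \code{\link{crossTraitRegression}} and
#' \code{\link{jackknifeVariance}}. With \code{constrain = TRUE} the
#' intercept is fixed at 0 with zero variance (only appropriate in
#' simulations known to have no overlap; the default never constrains).
#'
#' @inheritParams jackknifeVariance
#' @param constrain fix the intercept at zero (default FALSE).
#' @return a \code{\linkS4class{CrossTraitIntercept}}.
#' @export
estimateIntercept <- function(pair, scores, nBlocks = 200, weighted = TRUE,
                              constrain = FALSE) {
  if (constrain)
    return(new("CrossTraitIntercept", estimate = 0, variance = 0,
               slope = NA_real_, nBlocks = 0L))
  fit <- crossTraitRegression(pair, scores, weighted = weighted)
  v <- jackknifeVariance(pair, scores, nBlocks = nBlocks,
                         weighted = weighted)
  new("CrossTraitIntercept", estimate = unname(fit["intercept"]),
      variance = v, slope = unname(fit["slope"]),
      nBlocks = as.integer(nBlocks))
}
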