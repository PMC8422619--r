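## Local genetic covariance core. Within a block with LD eigenvalues w and
## decorrelated scores zt1, zt2, the model for the products is
##   E[zt1_j zt2_j]  = sqrt(n1 n2) rho_i / m_i * w_j^2 + a * w_j
##   Var[zt1_j zt2_j] ~ q_j^2 = (n1 h2_1i/m_i w_j^2 + w_j)
##                            * (n2 h2_2i/m_i w_j^2 + w_j)
## with a the overlap intercept. rho_i is recovered by no-intercept WLS of
## eta_j = zt1_j zt2_j - a w_j on w_j^2, using only the leading K_i
## components; K_i is chosen to minimize the larger of the theoretical and
## empirical variance of the estimator.

#' Method-of-moments local heritability
#'
#' Matches the empirical second moments of the decorrelated z scores to
#' their model expectation \eqn{E[\tilde z_j^2] = (n h^2/m_i) w_j^2 + w_j}
#' over the leading K components:
#' \deqn{\hat h^2 = m_i (\sum_{j\le K} \tilde z_j^2/w_j - K) / (n \sum_{j\le K} w_j).}
#'
#' @param zt decorrelated z scores.
#' @param w eigenvalues (positive on the used prefix).
#' @param n study sample size; \code{mi} block SNP count; \code{K}
#'   components used.
#' @param clip clip the estimate at 0 from below (default TRUE; the raw
#'   value is returned in attribute \code{"raw"}).
#' @return local heritability estimate.
#' @export
localH2MoM <- function(zt, w, n, mi, K = length(w), clip = TRUE) {
  if (K > length(w)) stop("K exceeds the number of components")
  wk <- w[seq_len(K)]
  if (any(wk <= 0)) stop("zero eigenvalue inside the leading K components")
  raw <- mi * (sum(zt[seq_len(K)]^2 / wk) - K) / (n * sum(wk))
  out <- if (clip) max(raw, 0) else raw
  attr(out, "raw") <- raw
  out
}

#' Per-component variance weights
#'
#' \code{q2_j = (n1 h2_1/m_i w_j^2 + w_j) (n2 h2_2/m_i w_j^2 + w_j)}, the
#' approximate variance of the decorrelated score product, whose
#' reciprocal is the WLS weight.
#'
#' @param w eigenvalues (> 0).
#' @param h21,h22 local heritabilities (clipped at 0).
#' @param n1,n2 sample sizes; \code{mi} block SNP count.
#' @return strictly positive numeric vector.
#' @export
momWeights <- function(w, h21, h22, n1, n2, mi) {
  (n1 * max(h21, 0) / mi * w^2 + w) * (n2 * max(h22, 0) / mi * w^2 + w)
}

#' Overlap-adjusted score products
#'
#' \code{eta_j = zt1_j * zt2_j - aHat * w_j}: the per-component product
#' with the expected sample-overlap contribution removed.
#'
#' @param zt1,zt2 decorrelated z scores.
#' @param w eigenvalues.
#' @param aHat cross-trait intercept estimate.
#' @return numeric vector.
#' @export
computeEta <- function(zt1, zt2, w, aHat) {
  stopifnot(length(zt1) == length(zt2), length(zt1) == length(w))
  zt1 * zt2 - aHat * w
}

#' No-intercept WLS estimate of local genetic covariance
#'
#' \deqn{\hat\rho_i = \frac{m_i}{\sqrt{n_1 n_2}}
#'   \frac{\sum_{j\le K} \eta_j w_j^2 / q_j^2}{\sum_{j\le K} w_j^4 / q_j^2}.}
#'
#' @param eta overlap-adjusted products; \code{w} eigenvalues; \code{q2}
#'   variance weights.
#' @param K leading components used (>= 2).
#' @param n1,n2 sample sizes; \code{mi} block SNP count.
#' @return local covariance estimate (observed scale).
#' @export
wlsRho <- function(eta, w, q2, K, n1, n2, mi) {
  j <- seq_len(K)
  den <- sum(w[j]^4 / q2[j])
  if (den <= 0 || !is.finite(den))
    stop("degenerate eigen spectrum: zero WLS denominator")
  mi / sqrt(n1 * n2) * sum(eta[j] * w[j]^2 / q2[j]) / den
}

#' Theoretical conditional variance of the local covariance estimate
#'
#' \deqn{Var[\hat\rho_i \mid \hat a] = \frac{m_i^2/(n_1 n_2)}
#'   {\sum_{j\le K} w_j^4/q_j^2},} nonincreasing in K.
#'
#' @inheritParams wlsRho
#' @export
theoreticalVar <- function(w, q2, K, n1, n2, mi) {
  j <- seq_len(K)
  (mi^2 / (n1 * n2)) / sum(w[j]^4 / q2[j])
}

#' Empirical (residual-based) conditional variance
#'
#' Theoretical variance times the weighted residual sum of squares of the
#' no-intercept fit over its K - 1 degrees of freedom:
#' \deqn{\hat{Var} = Var_{theo} \cdot
#'   \big[\sum \eta_j^2/q_j^2 - (\sum \eta_j w_j^2/q_j^2)^2 /
#'   \sum w_j^4/q_j^2\big] / (K-1).}
#' Nonnegative by Cauchy-Schwarz; exactly 0 when eta is proportional to
#' w^2.
#'
#' @inheritParams wlsRho
#' @export
empiricalVar <- function(eta, w, q2, K, n1, n2, mi) {
  if (K < 3) stop("empirical variance needs K >= 3")
  j <- seq_len(K)
  S4 <- sum(w[j]^4 / q2[j])
  rss <- sum(eta[j]^2 / q2[j]) - sum(eta[j] * w[j]^2 / q2[j])^2 / S4
  (mi^2 / (n1 * n2)) / S4 * max(rss, 0) / (K - 1)
}

#' Variance contributed by the estimated overlap intercept
#'
#' First-order propagation of the intercept's uncertainty into the local
#' estimate:
#' \deqn{\frac{m_i^2}{n_1 n_2}
#'   \Big(\frac{\sum w_j^3/q_j^2}{\sum w_j^4/q_j^2}\Big)^2 Var[\hat a].}
#'
#' @inheritParams wlsRho
#' @param varA variance of the intercept estimate (>= 0).
#' @export
interceptVarProp <- function(w, q2, K, n1, n2, mi, varA) {
  if (varA < 0) stop("varA must be >= 0")
  j <- seq_len(K)
  S3 <- sum(w[j]^3 / q2[j]); S4 <- sum(w[j]^4 / q2[j])
  mi^2 / (n1 * n2) * (S3 / S4)^2 * varA
}

#' Total variance by the law of total variance
#'
#' Sum of the conditional (residual-based) variance and the propagated
#' intercept variance.
#'
#' @param varConditional,varInterceptProp the two components (>= 0).
#' @export
totalVar <- function(varConditional, varInterceptProp) {
  stopifnot(varConditional >= 0, varInterceptProp >= 0)
  varConditional + varInterceptProp
}

#' Adaptive selection of the number of eigen-components
#'
#' Evaluates \code{v(K) = max(theoretical variance, empirical variance)}
#' for K from \code{kMin} (default 10; all components when the usable rank
#' is below that) up to the usable rank, and picks the minimizing K
#' (smallest K on ties). Local heritabilities entering the weights are
#' re-estimated at each candidate K from the truncated spectrum. All
#' estimator outputs are recomputed at the selected K.
#'
#' @param zt1,zt2 decorrelated z scores (full usable prefix, w > 0).
#' @param w matching positive eigenvalues.
#' @param n1,n2,mi sample sizes and block SNP count.
#' @param aHat,varA overlap intercept estimate and its variance.
#' @param kMin lower bound of the K grid (default 10).
#' @return list with \code{K}, \code{rho}, \code{varTheoretical},
#'   \code{varConditional} (empirical, Eq.-6-style; theoretical when the
#'   rank does not support a residual estimate), \code{varIntercept},
#'   \code{varTotal}, \code{h21}, \code{h22} (clipped) and
#'   \code{h21Raw}, \code{h22Raw}; or NULL if no candidate K yields a
#'   finite criterion (block not estimable).
#' @export
selectK <- function(zt1, zt2, w, n1, n2, mi, aHat, varA, kMin = 10L) {
  r <- length(w)
  stopifnot(length(zt1) == r, length(zt2) == r, all(w > 0), r >= 2)
  kGrid <- if (r <= kMin) r else seq.int(kMin, r)
  ## very long grids (pooled whole-genome regions) are thinned to ~512
  ## evaluation points; v(K) is smooth in K so the minimizer is barely
  ## affected while the search stays linear in memory
  if (length(kGrid) > 512L)
    kGrid <- unique(round(seq(kMin, r, length.out = 512L)))
  nK <- length(kGrid)
  eta <- zt1 * zt2 - aHat * w

  cz1 <- cumsum(zt1^2 / w); cz2 <- cumsum(zt2^2 / w); cw <- cumsum(w)
  h1Raw <- mi * (cz1[kGrid] - kGrid) / (n1 * cw[kGrid])
  h2Raw <- mi * (cz2[kGrid] - kGrid) / (n2 * cw[kGrid])
  h1K <- pmax(h1Raw, 0); h2K <- pmax(h2Raw, 0)

  A1 <- n1 * w^2 / mi; A2 <- n2 * w^2 / mi
  ## q2 for component j under candidate K: rows j, columns K
  Q <- (outer(A1, h1K) + w) * (outer(A2, h2K) + w)
  M <- outer(seq_len(r), kGrid, "<=")
  S4 <- colSums(w^4 / Q * M)
  S3 <- colSums(w^3 / Q * M)
  Se <- colSums(eta * w^2 / Q * M)
  S2e <- colSums(eta^2 / Q * M)

  varT <- (mi^2 / (n1 * n2)) / S4
  varE <- ifelse(kGrid >= 3,
                 varT * pmax(S2e - Se^2 / S4, 0) / (kGrid - 1),
                 NA_real_)
  v <- pmax(varT, varE, na.rm = TRUE)
  v[!is.finite(v)] <- Inf
  if (all(!is.finite(v)) || all(v == Inf)) return(NULL)
  kIdx <- which.min(v)  # first minimum = smallest K on ties

  K <- kGrid[kIdx]
  rho <- mi / sqrt(n1 * n2) * Se[kIdx] / S4[kIdx]
  varCond <- if (is.na(varE[kIdx])) varT[kIdx] else varE[kIdx]
  varInt <- mi^2 / (n1 * n2) * (S3[kIdx] / S4[kIdx])^2 * varA
  list(K = K, rho = rho,
       varTheoretical = varT[kIdx],
       varConditional = varCond,
       varIntercept = varInt,
       varTotal = varCond + varInt,
       h21 = h1K[kIdx], h22 = h2K[kIdx],
       h21Raw = h1Raw[kIdx], h22Raw = h2Raw[kIdx])
}

#' Two-sided normal (Wald) p value
#'
#' @param rho estimate; \code{varTotal} its variance (> 0).
#' @return p value in (0, 1]; NA with a warning when the variance is 0.
#' @export
waldTest <- function(rho, varTotal) {
  if (!is.finite(varTotal) || varTotal <= 0) {
    warning("waldTest: nonpositive variance; p value undefined")
    return(NA_real_)
  }
  2 * pnorm(-abs(rho) / sqrt(varTotal))
}

#' Local genetic correlation with delta-method standard error
#'
#' \code{corr = rho / sqrt(h21 * h22)}. The standard error treats the
#' three estimates as independent (first-order delta method). Undefined
#' (NA with a reason attribute) when either heritability is nonpositive,
#' where the ratio is numerically unstable.
#'
#' @param rho,varRho local covariance estimate and variance.
#' @param h21,h22 local heritabilities; \code{varH21}, \code{varH22} their
#'   variances (default 0: covariance-only uncertainty).
#' @return list \code{corr}, \code{se}; both NA when undefined.
#' @export
localCorrelation <- function(rho, varRho, h21, h22,
                             varH21 = 0, varH22 = 0) {
  if (!is.finite(h21) || !is.finite(h22) || h21 <= 0 || h22 <= 0) {
    out <- list(corr = NA_real_, se = NA_real_)
    attr(out, "reason") <- "nonpositive local heritability"
    return(out)
  }
  corr <- rho / sqrt(h21 * h22)
  se <- sqrt(varRho / (h21 * h22) +
             corr^2 / 4 * (varH21 / h21^2 + varH22 / h22^2))
  list(corr = corr, se = se)
}

#' Observed/liability scale conversion constant
#'
#' For two case-control studies with sample prevalences P1, P2 and
#' population prevalences K1, K2, observed-scale covariance equals
#' liability-scale covariance times
#' \deqn{c = \phi(\tau_1)\phi(\tau_2)\sqrt{P_1(1-P_1)P_2(1-P_2)} /
#'   [K_1(1-K_1)K_2(1-K_2)],}
#' with \eqn{\tau = \Phi^{-1}(1-K)} the liability threshold. The constant
#' is positive, so significance and direction are scale-invariant.
#'
#' @param P1,P2 sample prevalences in (0,1).
#' @param K1,K2 population prevalences in (0,1).
#' @return the positive constant c.
#' @export
liabilityConstant <- function(P1, K1, P2, K2) {
  stopifnot(P1 > 0, P1 < 1, P2 > 0, P2 < 1, K1 > 0, K1 < 1, K2 > 0, K2 < 1)
  t1 <- qnorm(1 - K1); t2 <- qnorm(1 - K2)
  dnorm(t1) * dnorm(t2) * sqrt(P1 * (1 - P1) * P2 * (1 - P2)) /
    (K1 * (1 - K1) * K2 * (1 - K2))
}

#' Convert observed-scale covariance to the liability scale
#'
#' Divides the observed-scale value by the conversion constant (see
#' \code{\link{liabilityConstant}}); sign is preserved.
#'
#' @param rhoObs observed-scale genetic covariance.
#' @inheritParams liabilityConstant
#' @export
liabilityConvert <- function(rhoObs, P1, K1, P2, K2) {
  rhoObs / liabilityConstant(P1, K1, P2, K2)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level; \code{nTests} number of tests (>= 1).
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(nTests >= 1)
  alpha / nTests
}

#' Benjamini-Hochberg discovery flags
#'
#' Step-up FDR control at level q (wraps \code{p.adjust}).
#'
#' @param p p values in (0, 1]; \code{q} FDR level.
#' @return logical vector of discoveries.
#' @export
bhFdr <- function(p, q) {
  p.adjust(p, method = "BH") <= q
}

#' Sampling variance of the method-of-moments local heritability
#'
#' Under the second-moment model \eqn{E[\tilde z_j^2] = (n h^2/m) w_j^2 +
#' w_j} with (approximately) normal decorrelated scores,
#' \eqn{Var[\tilde z_j^2] = 2 E[\tilde z_j^2]^2}; the MoM estimator is a
#' linear functional of those, giving
#' \deqn{Var[\hat h^2] = \Big(\frac{m}{n \sum_{j \le K} w_j}\Big)^2
#'   \sum_{j \le K} 2 ((n h^2/m) w_j + 1)^2.}
#' Used for the delta-method SE of local correlation.
#'
#' @inheritParams localH2MoM
#' @param h2 plug-in heritability value.
#' @export
varLocalH2 <- function(w, h2, n, mi, K = length(w)) {
  wk <- w[seq_len(K)]
  (mi / (n * sum(wk)))^2 * sum(2 * ((n * max(h2, 0) / mi) * wk + 1)^2)
}
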