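test_that("method-of-moments local heritability matches the moment identity", {
  w <- c(3, 2, 1.5, 1, 0.5)
  ## pure-null moments: zt^2 = w exactly -> h2 = 0
  expect_equal(localH2MoM(sqrt(w), w, n = 1000, mi = 50), 0,
               ignore_attr = TRUE)
  ## plug the model second moment in exactly -> recovers h2
  h2 <- 0.07; n <- 800; mi <- 40
  zt <- sqrt(n * h2 / mi * w^2 + w)
  est <- localH2MoM(zt, w, n, mi)
  expect_equal(as.numeric(est), h2, tolerance = 1e-12)
  ## negative raw estimate clipped, raw preserved
  ztlow <- sqrt(0.5 * w)
  est2 <- localH2MoM(ztlow, w, n, mi)
  expect_equal(as.numeric(est2), 0)
  expect_lt(attr(est2, "raw"), 0)
  expect_error(localH2MoM(zt, c(w[-5], 0), n, mi), "eigenvalue")
})

test_that("variance weights follow the printed product form", {
  w <- c(2, 1, 0.5)
  expect_equal(momWeights(w, 0, 0, 100, 100, 10), w^2)
  ## w = 1, n h2 / m = 0.5 each study -> (0.5 + 1)^2
  expect_equal(momWeights(1, 0.5 * 30 / 900, 0.5 * 30 / 900, 900, 900, 30),
               2.25, tolerance = 1e-12)
  ## strictly increasing in each heritability argument
  q0 <- momWeights(w, 0.1, 0.1, 500, 500, 20)
  expect_true(all(momWeights(w, 0.2, 0.1, 500, 500, 20) > q0))
  expect_true(all(momWeights(w, 0.1, 0.2, 500, 500, 20) > q0))
})

test_that("overlap-adjusted products subtract aHat * w", {
  z1 <- c(1, 2, -1); z2 <- c(0.5, -1, 2); w <- c(3, 2, 1)
  expect_equal(computeEta(z1, z2, w, 0), z1 * z2)
  expect_equal(computeEta(rep(0, 3), z2, w, 0.4), -0.4 * w)
  expect_equal(computeEta(z1, (0.4 * w) / z1, w, 0.4), rep(0, 3),
               tolerance = 1e-12)
})

test_that("wlsRho matches hand computation and a dense WLS oracle", {
  ## hand case: slope (4*4 + 1*1)/(16 + 1) = 1, rho = m/sqrt(n1 n2) = 2
  expect_equal(wlsRho(eta = c(4, 1), w = c(2, 1), q2 = c(1, 1), K = 2,
                      n1 = 1, n2 = 1, mi = 2), 2, tolerance = 1e-12)
  expect_equal(wlsRho(rep(0, 5), 5:1, rep(1, 5), 5, 100, 100, 20), 0)

  set.seed(99)
  for (i in 1:100) {
    K <- sample(3:12, 1)
    w <- sort(runif(K, 0.1, 4), decreasing = TRUE)
    eta <- rnorm(K); q2 <- runif(K, 0.2, 3)
    n1 <- sample(100:1000, 1); n2 <- sample(100:1000, 1)
    mi <- sample(10:200, 1)
    fit <- lm(eta ~ 0 + I(w^2), weights = 1 / q2)
    oracle <- mi / sqrt(n1 * n2) * unname(coef(fit))
    expect_equal(wlsRho(eta, w, q2, K, n1, n2, mi), oracle,
                 tolerance = 1e-10)
  }
})

test_that("theoretical variance follows the closed form and is monotone", {
  expect_equal(theoreticalVar(c(1, 1), c(1, 1), 2, 1, 1, 1), 0.5)
  ## doubling m quadruples
  v1 <- theoreticalVar(c(2, 1), c(1.5, 1), 2, 300, 400, 50)
  expect_equal(theoreticalVar(c(2, 1), c(1.5, 1), 2, 300, 400, 100),
               4 * v1, tolerance = 1e-12)
  set.seed(12)
  w <- sort(runif(20, 0.1, 4), decreasing = TRUE)
  q2 <- runif(20, 0.5, 2)
  v <- vapply(2:20, function(K) theoreticalVar(w, q2, K, 100, 100, 10),
              numeric(1))
  expect_true(all(diff(v) <= 0))
})

test_that("empirical variance is the residual-scaled form, >= 0, 0 at fit", {
  ## eta exactly proportional to w^2 -> zero residual
  w <- c(2, 1.5, 1)
  expect_equal(empiricalVar(3 * w^2, w, rep(1, 3), 3, 10, 10, 5), 0,
               tolerance = 1e-12)
  expect_equal(empiricalVar(rep(0, 4), c(2, 1.5, 1, 0.5), rep(1, 4), 4,
                            10, 10, 5), 0)
  expect_error(empiricalVar(c(1, 2), c(2, 1), c(1, 1), 2, 10, 10, 5),
               "K >= 3")
  set.seed(13)
  for (i in 1:50) {
    K <- sample(3:15, 1)
    w <- sort(runif(K, 0.1, 3), decreasing = TRUE)
    eta <- rnorm(K); q2 <- runif(K, 0.3, 2)
    v <- empiricalVar(eta, w, q2, K, 200, 300, 30)
    expect_gte(v, 0)
    ## oracle: weighted no-intercept lm residual variance times (X'WX)^-1
    fit <- lm(eta ~ 0 + I(w^2), weights = 1 / q2)
    oracle <- (30^2 / (200 * 300)) * sum(1 / q2 * residuals(fit)^2) /
      (K - 1) / sum(w^4 / q2)
    expect_equal(v, oracle, tolerance = 1e-10)
  }
})

test_that("intercept-variance propagation matches its closed form", {
  w <- c(2, 1); q2 <- c(1.2, 0.8)
  expect_equal(interceptVarProp(w, q2, 2, 100, 100, 10, 0), 0)
  ## identity-LD limit: all eigenvalues 1 -> (m^2/(n1 n2)) * varA
  expect_equal(interceptVarProp(rep(1, 6), runif(6, 0.5, 2), 6,
                                50, 80, 12, 0.3),
               12^2 / (50 * 80) * 0.3, tolerance = 1e-12)
  v1 <- interceptVarProp(w, q2, 2, 100, 100, 10, 0.1)
  expect_equal(interceptVarProp(w, q2, 2, 100, 100, 10, 0.2), 2 * v1,
               tolerance = 1e-12)
  ## numerical-derivative oracle: variance of rho wrt the intercept
  set.seed(14)
  for (i in 1:20) {
    K <- sample(3:10, 1)
    w <- sort(runif(K, 0.2, 3), decreasing = TRUE)
    q2 <- runif(K, 0.3, 2); varA <- runif(1, 0, 0.5)
    n1 <- 150; n2 <- 250; mi <- 40
    zt1 <- rnorm(K); zt2 <- rnorm(K)
    drho <- (wlsRho(computeEta(zt1, zt2, w, 1e-5), w, q2, K, n1, n2, mi) -
             wlsRho(computeEta(zt1, zt2, w, -1e-5), w, q2, K, n1, n2, mi)) /
      2e-5
    expect_equal(interceptVarProp(w, q2, K, n1, n2, mi, varA),
                 drho^2 * varA, tolerance = 1e-6)
  }
})

test_that("total variance is the sum of its two components", {
  expect_equal(totalVar(0.1, 0.05), 0.15)
  expect_equal(totalVar(0.3, 0), 0.3)
  expect_equal(totalVar(0.2, 0.7), totalVar(0.7, 0.2))
  expect_error(totalVar(-0.1, 0.05))
})

test_that("adaptive K selection minimizes v(K) with smallest-K ties", {
  ## oracle: direct loop over the K grid, re-estimating h2 at each K
  vOracle <- function(zt1, zt2, w, n1, n2, mi, aHat, kMin = 10L) {
    r <- length(w)
    grid <- if (r <= kMin) r else kMin:r
    eta <- computeEta(zt1, zt2, w, aHat)
    v <- vapply(grid, function(K) {
      h1 <- localH2MoM(zt1, w, n1, mi, K)
      h2 <- localH2MoM(zt2, w, n2, mi, K)
      q2 <- momWeights(w, h1, h2, n1, n2, mi)
      vt <- theoreticalVar(w, q2, K, n1, n2, mi)
      if (K >= 3) max(vt, empiricalVar(eta, w, q2, K, n1, n2, mi)) else vt
    }, numeric(1))
    grid[which.min(v)]
  }
  set.seed(15)
  for (i in 1:20) {
    r <- sample(c(6, 15, 40), 1)
    w <- sort(runif(r, 0.2, 4), decreasing = TRUE)
    zt1 <- rnorm(r, sd = sqrt(w)); zt2 <- rnorm(r, sd = sqrt(w))
    n1 <- 400; n2 <- 600; mi <- r
    fit <- selectK(zt1, zt2, w, n1, n2, mi, aHat = 0.05, varA = 0.01)
    expect_equal(fit$K, vOracle(zt1, zt2, w, n1, n2, mi, 0.05))
    ## reported pieces are consistent at the selected K
    h1 <- localH2MoM(zt1, w, n1, mi, fit$K)
    h2 <- localH2MoM(zt2, w, n2, mi, fit$K)
    q2 <- momWeights(w, h1, h2, n1, n2, mi)
    eta <- computeEta(zt1, zt2, w, 0.05)
    expect_equal(fit$rho, wlsRho(eta, w, q2, fit$K, n1, n2, mi),
                 tolerance = 1e-10)
    expect_equal(fit$varIntercept,
                 interceptVarProp(w, q2, fit$K, n1, n2, mi, 0.01),
                 tolerance = 1e-10)
    expect_equal(fit$varTotal, fit$varConditional + fit$varIntercept)
  }
  ## blocks smaller than the lower bound use all components
  wS <- c(2, 1, 0.5)
  fS <- selectK(rnorm(3), rnorm(3), wS, 100, 100, 3, 0, 0)
  expect_equal(fS$K, 3L)
})

test_that("Wald test is two-sided normal and symmetric", {
  expect_equal(waldTest(0, 1), 1)
  expect_equal(waldTest(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(waldTest(-0.7, 0.3), waldTest(0.7, 0.3))
  expect_warning(p <- waldTest(1, 0), "undefined")
  expect_true(is.na(p))
})

test_that("local correlation normalizes by heritabilities with a guard", {
  expect_equal(localCorrelation(0, 0.1, 0.2, 0.3)$corr, 0)
  expect_equal(localCorrelation(0.5, 0.1, 1, 0.25)$corr, 1)
  und <- localCorrelation(0.5, 0.1, -0.01, 0.25)
  expect_true(is.na(und$corr))
  expect_match(attr(und, "reason"), "heritability")
  ## delta-method SE reduces to sd(rho)/sqrt(h1 h2) when h2s are exact
  ct <- localCorrelation(0.3, 0.04, 0.5, 0.2)
  expect_equal(ct$se, sqrt(0.04 / 0.1), tolerance = 1e-12)
})

test_that("liability conversion constant and round trip", {
  cc <- liabilityConstant(0.5, 0.5, 0.5, 0.5)
  expect_equal(cc, dnorm(0)^2 * 0.25 / 0.0625, tolerance = 1e-12)
  expect_equal(liabilityConvert(0, 0.3, 0.1, 0.4, 0.05), 0)
  set.seed(16)
  for (i in 1:20) {
    P1 <- runif(1, 0.1, 0.9); P2 <- runif(1, 0.1, 0.9)
    K1 <- runif(1, 0.01, 0.5); K2 <- runif(1, 0.01, 0.5)
    rho <- rnorm(1)
    expect_gt(liabilityConstant(P1, K1, P2, K2), 0)
    back <- liabilityConvert(rho, P1, K1, P2, K2) *
      liabilityConstant(P1, K1, P2, K2)
    expect_equal(back, rho, tolerance = 1e-12)
  }
})

test_that("multiple-testing helpers", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.1, 4), 0.025)
  expect_equal(bhFdr(rep(1, 5), 0.1), rep(FALSE, 5))
  expect_equal(bhFdr(c(0.01, 0.02, 0.9), 0.1), c(TRUE, TRUE, FALSE))
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  expect_true(all(bhFdr(p, 0.05) >= bhFdr(p, 0.01)))
})
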