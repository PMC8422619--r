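test_that("genotype generation is deterministic and margin-exact", {
  cfg <- simConfig(n1 = 300, n2 = 300, nRef = 100,
                   blockSizes = rep(40L, 4L), ldR = 0.5, seed = 42)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(g1$study1, g2$study1)
  expect_identical(g1$ref, g2$ref)
  ## different seed, different panels
  g3 <- simulateGenotypes(simConfig(n1 = 300, n2 = 300, nRef = 100,
                                    blockSizes = rep(40L, 4L), ldR = 0.5,
                                    seed = 43))
  expect_false(identical(g1$study1, g3$study1))
  ## realized allele frequencies track the drawn MAFs
  f <- colMeans(g1$study1) / 2
  expect_lt(max(abs(f - g1$maf)), 0.12)
})

test_that("adjacent-SNP correlation hits the generator target", {
  ## equal MAFs keep the Bernoulli feasibility bound inactive
  cfg <- simConfig(n1 = 5000, n2 = 100, ns = 0, nRef = 10,
                   blockSizes = 200L, mafRange = c(0.3, 0.3),
                   ldR = 0.9, seed = 42)
  g <- simulateGenotypes(cfg)
  cm <- cor(g$study1)
  adj <- cm[cbind(1:199, 2:200)]
  expect_lt(abs(mean(adj) - 0.9), 0.02)
  ## r = 0: independence
  cfg0 <- simConfig(n1 = 5000, n2 = 100, ns = 0, nRef = 10,
                    blockSizes = 200L, ldR = 0, seed = 42)
  adj0 <- cor(simulateGenotypes(cfg0)$study1)[cbind(1:199, 2:200)]
  expect_lt(max(abs(adj0)), 0.08)
  ## chains restart at block boundaries: cross-block correlation ~ 0
  cfgB <- simConfig(n1 = 5000, n2 = 100, ns = 0, nRef = 10,
                    blockSizes = c(100L, 100L), mafRange = c(0.3, 0.3),
                    ldR = 0.9, seed = 42)
  gB <- simulateGenotypes(cfgB)
  expect_lt(abs(cor(gB$study1[, 100], gB$study1[, 101])), 0.05)
})

test_that("shared samples have identical genotypes across cohorts", {
  cfg <- simConfig(n1 = 100, n2 = 120, ns = 30, nRef = 50,
                   blockSizes = rep(20L, 3L), seed = 7)
  g <- simulateGenotypes(cfg)
  expect_identical(g$study1[1:30, ], g$study2[1:30, ])
  expect_false(identical(g$study1[31:60, ], g$study2[31:60, ]))
})

test_that("effect draws match the configured second moments", {
  m <- 100000L
  cfg <- simConfig(n1 = 10, n2 = 10, nRef = 10, blockSizes = m,
                   mode = "global", rhoGlobal = 0.2, h2 = c(0.5, 0.4),
                   seed = 5)
  set.seed(5)
  eff <- drawEffects(cfg)
  expect_equal(var(eff$beta) * m, 0.5, tolerance = 0.02)
  expect_equal(var(eff$gamma) * m, 0.4, tolerance = 0.02)
  expect_equal(cov(eff$beta, eff$gamma) * m, 0.2, tolerance = 0.02)

  ## local mode: covariance only inside the target block
  cfgL <- simConfig(n1 = 10, n2 = 10, nRef = 10,
                    blockSizes = c(20000L, 80000L), targetBlock = 1L,
                    rhoLocal = 0.004, seed = 5)
  set.seed(5)
  effL <- drawEffects(cfgL)
  inT <- 1:20000
  covT <- sum(effL$beta[inT] * effL$gamma[inT]) -
    20000 * mean(effL$beta[inT]) * mean(effL$gamma[inT])
  expect_lt(abs(covT - 0.004), 0.0025)
  expect_lt(abs(cor(effL$beta[-inT], effL$gamma[-inT])), 0.01)

  ## degenerate bivariate normal: perfectly proportional effects
  cfgD <- simConfig(n1 = 10, n2 = 10, nRef = 10, blockSizes = 1000L,
                    mode = "global", rhoGlobal = 0.5, h2 = c(0.5, 0.5),
                    seed = 5)
  effD <- drawEffects(cfgD)
  expect_equal(cor(effD$beta, effD$gamma), 1, tolerance = 1e-12)
})

test_that("phenotypes have unit variance and configured shared-noise cov", {
  cfg <- simConfig(n1 = 4000, n2 = 4000, ns = 4000, nRef = 10,
                   blockSizes = 50L, h2 = c(0, 0), rhoE = 0.2, seed = 9)
  g <- simulateGenotypes(cfg)
  X1 <- standardizeGenotypes(g$study1); X2 <- standardizeGenotypes(g$study2)
  set.seed(1)
  ph <- simulatePhenotypes(X1, X2, rep(0, 50), rep(0, 50), cfg)
  expect_equal(sd(ph$phi1), 1, tolerance = 1e-12)   # rescaled exactly
  expect_lt(abs(cov(ph$phi1, ph$phi2) - 0.2), 0.05)
  ## no overlap: independent noise
  cfg0 <- simConfig(n1 = 4000, n2 = 4000, ns = 0, nRef = 10,
                    blockSizes = 50L, h2 = c(0, 0), rhoE = 0, seed = 9)
  g0 <- simulateGenotypes(cfg0)
  set.seed(1)
  ph0 <- simulatePhenotypes(standardizeGenotypes(g0$study1),
                            standardizeGenotypes(g0$study2),
                            rep(0, 50), rep(0, 50), cfg0)
  expect_lt(abs(cov(ph0$phi1, ph0$phi2)), 0.05)
})

test_that("z scores follow the score-statistic model", {
  set.seed(2)
  X <- standardizeGenotypes(matrix(rbinom(500 * 20, 2, 0.4), 500, 20))
  phi <- rnorm(500); phi <- phi / sd(phi)
  z <- runGwas(X, phi)
  expect_equal(z, drop(crossprod(X, phi)) / sqrt(500), tolerance = 1e-12)
  ## orthogonal phenotype -> zero z
  phiO <- phi - X[, 1] * sum(X[, 1] * phi) / sum(X[, 1]^2)
  expect_equal(runGwas(X, phiO)[1], 0, tolerance = 1e-12)

  ## E[z_j^2] ~ (n h2 / m) * ldscore_j + 1 across replicates
  cfg <- simConfig(n1 = 800, n2 = 100, ns = 0, nRef = 300,
                   blockSizes = c(30L, 30L), h2 = c(0.4, 0.4),
                   ldR = c(0.5, 0.8), seed = 21)
  eng <- cachedEngine("zmom", cfg)
  acc <- numeric(60)
  nrep <- 300
  for (r in seq_len(nrep)) {
    set.seed(100 + r)
    eff <- drawEffects(cfg)
    ph <- simulatePhenotypes(eng$X1, eng$X2, eff$beta, eff$gamma, cfg)
    acc <- acc + runGwas(eng$X1, ph$phi1)^2
  }
  pred <- 800 * 0.4 / 60 * eng$ldScores + 1
  expect_equal(mean(acc / nrep), mean(pred), tolerance = 0.1)
  ## null trait: Var(z) ~ 1
  cfg0 <- simConfig(n1 = 800, n2 = 100, ns = 0, nRef = 300,
                    blockSizes = c(30L, 30L), h2 = c(0, 0), seed = 21)
  eng0 <- cachedEngine("zmom0", cfg0)
  set.seed(3)
  eff0 <- drawEffects(cfg0)
  ph0 <- simulatePhenotypes(eng0$X1, eng0$X2, eff0$beta, eff0$gamma, cfg0)
  z0 <- runGwas(eng0$X1, ph0$phi1)
  expect_equal(mean(z0^2), 1, tolerance = 0.4)
})

test_that("simulateStudyPair writes a consistent, reproducible fixture", {
  cfg <- simConfig(n1 = 200, n2 = 200, nRef = 120,
                   blockSizes = rep(30L, 3L), rhoLocal = 0, seed = 33)
  d1 <- file.path(tempdir(), "sp1"); d2 <- file.path(tempdir(), "sp2")
  a <- simulateStudyPair(cfg, dir = d1)
  b <- simulateStudyPair(cfg, dir = d2)
  expect_identical(a$sumstats1, b$sumstats1)
  expect_identical(readLines(a$paths$sumstats1),
                   readLines(b$paths$sumstats1))
  ## panel written to PLINK round-trips
  back <- readPlink(a$paths$bfile)
  expect_equal(unname(back$genotypes), unname(a$panels$ref))
  ## truth record carries the generative parameters
  truth <- jsonlite::read_json(a$paths$truth)
  expect_equal(truth$rhoLocal, 0)
  expect_equal(truth$seed, 33)
  expect_equal(truth$ns, 0)
})

test_that("replicateExperiment is deterministic and summarizes correctly", {
  cfg <- simConfig(n1 = 300, n2 = 300, nRef = 150,
                   blockSizes = rep(30L, 4L), rhoLocal = 0,
                   ldR = c(0.4, 0.8), seed = 77)
  eng <- cachedEngine("repexp", cfg)
  r1 <- suppressWarnings(replicateExperiment(cfg, 10, engine = eng))
  r2 <- suppressWarnings(replicateExperiment(cfg, 10, engine = eng))
  expect_identical(r1$estimates, r2$estimates)
  expect_equal(r1$summary$nReps, 10)
  expect_equal(r1$summary$bias, r1$summary$mean)
  expect_equal(r1$summary$rejectRate, mean(r1$pvalues < 0.05))
  ## engine compatibility is enforced
  other <- simConfig(n1 = 301, n2 = 300, nRef = 150,
                     blockSizes = rep(30L, 4L), seed = 77)
  expect_error(replicateExperiment(other, 5, engine = eng),
               "incompatible")
})
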