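test_that("simulation is reproducible and prefix-stable in the replicate count", {
  p <- refParams(1)
  cfgA <- sdeConfig(300, tOut = c(0.5, 2), seed = 9, landscapeMode = "full")
  e1 <- simulateLineages(p, cfgA)
  e2 <- simulateLineages(p, cfgA)
  expect_identical(e1@x1, e2@x1)
  expect_identical(e1@x2p, e2@x2p)
  # growing nReps appends without reshuffling earlier replicates
  eBig <- simulateLineages(p, sdeConfig(1400, tOut = c(0.5, 2), seed = 9,
                                        landscapeMode = "full"))
  expect_identical(eBig@x1[1:300, ], e1@x1)
})

test_that("config validation: tOut ordering, dt warning, mode names", {
  expect_error(sdeConfig(100, tOut = c(2, 1), seed = 1), "increasing")
  expect_error(sdeConfig(0, tOut = 1, seed = 1), "nReps")
  p <- refParams(100)  # 4*Ne*kappa ~ 100: bound ~ 1e-3
  expect_warning(simulateLineages(p, sdeConfig(50, tOut = 0.05, seed = 1,
                                               dt = 0.05)),
                 "bound")
})

test_that("drift: cusp convention, full/linearised agreement on the positive branch", {
  p <- refParams(1)
  lc <- landscapeConstants(p)
  # cusp: sign(0) = 0 gives zero drift at x1 = x2 in full mode
  expect_equal(lineageDrift(1, 1, p, "full")$d1, 0)
  # fixed point of the separation at xi0
  d <- lineageDrift(lc@xi0, 0, p, "linearised")
  expect_equal(d$d1, 0, tolerance = 1e-12)
  expect_equal(d$d2, 0, tolerance = 1e-12)
  # equality wherever x1 - x2 > 0; sign flip below the cusp
  x1 <- c(2.3, 0.4, 5); x2 <- c(0, 0.1, 1)
  expect_equal(lineageDrift(x1, x2, p, "full"),
               lineageDrift(x1, x2, p, "linearised"))
  # s = -0.5 (inside the cusp valley): full mode pushes out toward the
  # -xi0 well (s decreases), linearised pushes up toward +xi0
  full <- lineageDrift(0, 0.5, p, "full")$d1
  lin <- lineageDrift(0, 0.5, p, "linearised")$d1
  expect_true(full < 0 && lin > 0)
  # s = -2 (beyond the -xi0 well): both relax |s| back toward xi0
  expect_gt(lineageDrift(0, 2, p, "full")$d1, 0)
})

test_that("near-neutral landscape gives pure diffusion with independent components", {
  # kappa = 1/(ell*Ne) made negligible: variance grows as mu*t per component
  p <- modelParams(1000, 0, 1000, xiStar = 600)
  ens <- simulateLineages(p, sdeConfig(4000, tOut = 1, seed = 1,
                                       landscapeMode = "linearised"))
  v <- var(ens@x1[, 1])
  expect_lt(abs(v - 1) / (v * sqrt(2 / 3999)), 3)
  # component noises are independent
  cc <- cor(ens@x1[, 1] - mean(ens@x1[, 1]), ens@x2[, 1] - mean(ens@x2[, 1]))
  expect_lt(abs(cc), 3 / sqrt(4000))
})

test_that("linearised lineage recovers the Gaussian equilibrium law", {
  p <- refParams(1)
  lc <- landscapeConstants(p)
  ens <- simulateLineages(p, sdeConfig(4000, tOut = 10, seed = 1,
                                       landscapeMode = "linearised"))
  xi <- ens@x1[, 1] - ens@x2[, 1]
  n <- length(xi)
  expect_lt(abs(mean(xi) - lc@xi0) / (sd(xi) / sqrt(n)), 3)
  vTh <- 1 / (4 * popSize(p) * lc@kappa)
  expect_lt(abs(var(xi) - vTh) / (vTh * sqrt(2 / (n - 1))), 3)
  # centre of mass stays put in the mean
  com <- ens@x1[, 1] + ens@x2[, 1]
  expect_lt(abs(mean(com) - lc@xi0) / (sd(com) / sqrt(n)), 3)
})

test_that("hybrids start at xi0 exactly and diffuse at rate 2*mu at short times", {
  p <- refParams(1)
  lc <- landscapeConstants(p)
  ens <- simulateLineages(p, sdeConfig(4000, tOut = c(0, 0.05, 2), seed = 1,
                                       landscapeMode = "linearised"))
  h <- hybridEnergies(ens)
  expect_true(all(h$w[, 1] == lc@xi0))
  expect_true(all(h$wPrime[, 1] == lc@xi0))
  v <- var(h$w[, 2])
  th <- hybridCovariance(0.05, p)$sigma11  # ~ 2*mu*t
  expect_lt(abs(v - th) / (th * sqrt(2 / 3999)), 3)
  expect_lt(abs(th / 0.05 - 2), 0.1)
})

test_that("the two hybrids become anti-correlated once the landscape is felt", {
  p <- refParams(10)  # 8*Ne*kappa ~ 20.8: tau = 2 is deep in saturation
  ens <- simulateLineages(p, sdeConfig(2000, tOut = 2, seed = 1,
                                       landscapeMode = "linearised"))
  h <- hybridEnergies(ens)
  expect_lt(cor(h$w[, 1], h$wPrime[, 1]), -0.3)
})

test_that("empirical P_I matches the closed form in linearised mode", {
  p <- refParams(1)
  tau <- c(5, 10)
  ens <- simulateLineages(p, sdeConfig(4000, tOut = tau, seed = 1,
                                       landscapeMode = "linearised"))
  est <- empiricalPI(ens)
  th <- dmiProbability(tau, p)
  z <- abs(piValues(est) - th) / pmax(piStandardError(est), 1e-12)
  expect_true(all(z < 3))
  # pooled estimator: same mean within combined error, SE attached
  pooled <- empiricalPI(ens, estimator = "pooled")
  expect_true(all(abs(piValues(pooled) - piValues(est)) <
                    3 * sqrt(piStandardError(pooled)^2 +
                             piStandardError(est)^2) + 1e-12))
})

test_that("independent seeds agree within Monte-Carlo error", {
  p <- refParams(0.1)
  tau <- c(1, 5)
  pa <- empiricalPI(simulateLineages(p, sdeConfig(2000, tOut = tau, seed = 101,
                                                  landscapeMode = "full")))
  pb <- empiricalPI(simulateLineages(p, sdeConfig(2000, tOut = tau, seed = 202,
                                                  landscapeMode = "full")))
  comb <- sqrt(piStandardError(pa)^2 + piStandardError(pb)^2)
  expect_true(all(abs(piValues(pa) - piValues(pb)) <= 3 * comb))
})

test_that("halving dt moves the estimate by less than its Monte-Carlo error", {
  p <- refParams(1)
  pa <- empiricalPI(simulateLineages(p, sdeConfig(3000, tOut = 5, seed = 5,
                                                  landscapeMode = "full")))
  pb <- empiricalPI(simulateLineages(p, sdeConfig(3000, tOut = 5, seed = 5,
                                                  dt = 0.005,
                                                  landscapeMode = "full")))
  expect_lt(abs(piValues(pa) - piValues(pb)), piStandardError(pa))
})

test_that("reflecting boundary keeps lineage separations inside the viable strip", {
  p <- refParams(0.01)  # wide equilibrium: xi0 ~ 4.9, xi* ~ 7.07
  ens <- simulateLineages(p, sdeConfig(500, tOut = c(1, 5, 20), seed = 1,
                                       landscapeMode = "full",
                                       boundaryMode = "reflect"))
  expect_true(all(abs(ens@x1 - ens@x2) <= xiStar(p)))
  expect_true(all(abs(ens@x1p - ens@x2p) <= xiStar(p)))
})

test_that("equilibrium-sampled ancestors start with the equilibrium spread", {
  p <- refParams(1)
  lc <- landscapeConstants(p)
  ens <- simulateLineages(p, sdeConfig(4000, tOut = 0, seed = 1,
                                       landscapeMode = "linearised",
                                       initMode = "sample_equilibrium"))
  xi0samp <- ens@x1[, 1] - ens@x2[, 1]
  # both lineages share the ancestor state exactly
  expect_identical(ens@x1[, 1], ens@x1p[, 1])
  vTh <- lc@deltaXi^2
  expect_lt(abs(var(xi0samp) - vTh) / (vTh * sqrt(2 / 3999)), 3)
  expect_lt(abs(mean(xi0samp) - lc@xi0) / (sd(xi0samp) / sqrt(4000)), 3)
})
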