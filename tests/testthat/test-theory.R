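test_that("propagator is the identity at t=0, stochastic at all t, uniform at t=Inf", {
  p <- refParams(1)
  expect_equal(propagatorJ(0, p), diag(2))
  for (t in c(0.01, 0.5, 3, 50)) {
    J <- propagatorJ(t, p)
    expect_equal(rowSums(J), c(1, 1))
    expect_equal(J[1, 2], J[2, 1])
  }
  expect_equal(propagatorJ(1e6, p), matrix(0.5, 2, 2))
  expect_error(propagatorJ(-1, p), "nonnegative")
})

test_that("mean solution: xi0 fixed point, relaxation from 0, conserved centre of mass", {
  p <- refParams(1)
  x0sep <- optimalBindingEnergy(p)
  for (t in c(0, 0.3, 2, 20)) {
    m <- meanSolution(t, c(x0sep, 0), p)
    expect_equal(m[1] - m[2], x0sep, tolerance = 1e-12)
    # centre of mass has no drift in the mean
    expect_equal(sum(m), x0sep, tolerance = 1e-12)
  }
  mInf <- meanSolution(1e4, c(0, 0), p)
  expect_equal(mInf[1] - mInf[2], 1 / (2 * freeFitnessCurvature(p) * 100),
               tolerance = 1e-10)
})

test_that("hybrid mean is xi0 for all t, with its neutral and large-Ne limits", {
  p <- refParams(1)
  expect_equal(hybridMean(c(0, 1, 100), p),
               rep(optimalBindingEnergy(p), 3))
  # kappaF = 0: xi0 = ell/2
  expect_equal(hybridMean(1, modelParams(10, 0, 100, xiStar = 7)), 5)
  # selection dominated: xi0 -> 0
  expect_lt(hybridMean(1, modelParams(10, 1, 1e7, xiStar = 7)), 1e-4)
})

test_that("hybrid covariance: 2*mu*t onset, uncorrelated then anti-correlated", {
  p <- refParams(1)
  expect_equal(hybridCovariance(0, p)$sigma11, 0)
  expect_equal(hybridCovariance(0, p)$sigma12, 0)
  tiny <- hybridCovariance(1e-8, p)
  expect_equal(tiny$sigma11 / 1e-8, 2, tolerance = 1e-6)
  expect_lt(abs(tiny$sigma12 / tiny$sigma11), 1e-6)
  # long times: correlation -> -1
  a8 <- 8 * 100 * freeFitnessCurvature(p)
  long <- hybridCovariance(100 / a8 * 10, p)
  expect_lt(long$sigma12 / long$sigma11, -0.99)
  # positive semidefinite 2x2 at all times
  hm <- hybridCovariance(10^seq(-4, 3, by = 0.5), p)
  expect_true(all(hm$sigma11 >= 0))
  expect_true(all(abs(hm$sigma12) <= hm$sigma11 + 1e-12))
})

test_that("mean hybrid fitness equals -kappaF<w^2>/2 and has the predicted slopes", {
  p <- refParams(1)
  t <- c(0.001, 0.1, 1, 5, 40)
  hm <- hybridCovariance(t, p)
  kF <- fitnessCurvature(p)
  direct <- hybridFitnessMean(t, p)
  fromMoments <- -0.5 * kF * (hm$sigma11 + hm$meanW^2)
  expect_equal(direct, fromMoments, tolerance = 1e-10)
  # short-time slope -mu*kappaF; saturated slope -mu*kappaF/2
  h <- 1e-7
  slope0 <- (hybridFitnessMean(h, p) - hybridFitnessMean(0, p)) / h
  expect_equal(slope0, -1 * kF, tolerance = 1e-4)
  tBig <- 1e4
  slopeInf <- (hybridFitnessMean(tBig + 1, p) - hybridFitnessMean(tBig, p))
  expect_equal(slopeInf, -0.5 * kF, tolerance = 1e-8)
  # neutral landscape: constant
  expect_equal(hybridFitnessMean(c(0, 5, 50), modelParams(10, 0, 100, xiStar = 7)),
               rep(0, 3))
})

test_that("DMI probability: limits, Gaussian-quadrature oracle, monotonicity", {
  p <- refParams(1)
  expect_equal(dmiProbability(0, p), 0)
  # saturation to 1 is diffusive, ~ xi*/sqrt(Sigma11)
  expect_equal(dmiProbability(1e12, p), 1, tolerance = 1e-4)
  # oracle: P_I = 1 - integral of the Gaussian density over [-xi*, xi*]
  for (t in c(0.05, 1, 5, 20)) {
    hm <- hybridCovariance(t, p)
    q <- integrate(dnorm, -xiStar(p), xiStar(p), mean = hm$meanW,
                   sd = sqrt(hm$sigma11), rel.tol = 1e-13, abs.tol = 1e-14)
    expect_lt(abs(dmiProbability(t, p) - (1 - q$value)), 1e-10)
  }
  # relative agreement where the quadrature itself resolves the tail
  hm <- hybridCovariance(20, p)
  q <- integrate(dnorm, -xiStar(p), xiStar(p), mean = hm$meanW,
                 sd = sqrt(hm$sigma11), rel.tol = 1e-13)
  expect_equal(dmiProbability(20, p), 1 - q$value, tolerance = 1e-8)
  pi <- dmiProbability(10^seq(-3, 3, length.out = 60), p)
  expect_true(all(diff(pi) >= 0))
  expect_true(all(pi >= 0 & pi <= 1))
})

test_that("log-log curvature: zero for power laws, negative for the erfc onset", {
  t <- 10^seq(-3, 0, length.out = 30)
  expect_lt(max(abs(logLogCurvature(t, 3 * t^2.5))), 1e-8)
  # erfc(1/sqrt(t)) shape has an essential singularity at t = 0
  erfcCurve <- 2 * pnorm(sqrt(2) / sqrt(t), lower.tail = FALSE)
  expect_true(all(logLogCurvature(t, erfcCurve) < 0))
  p <- refParams(1)
  pi <- dmiProbability(t, p)
  expect_true(all(logLogCurvature(t, pi) < 0))
})

test_that("P_I depends only on the dimensionless products", {
  tau <- 10^seq(-2, 1, length.out = 20)
  # rescale mu and t inversely
  pA <- refParams(1, mu = 1)
  pB <- refParams(1, mu = 10)
  expect_equal(dmiProbability(tau / 1, pA), dmiProbability(tau / 10, pB),
               tolerance = 1e-12)
  # same (4*kappaF*Ne, ell, F*/kappaF) realised with different Ne
  pC <- modelParams(10, kappaF = 1 / 800, Ne = 200, fstarOverKappaF = -25)
  expect_equal(dmiProbability(tau, refParams(1)), dmiProbability(tau, pC),
               tolerance = 1e-12)
})

test_that("population-size ordering and extreme-Ne saturation of the analytic curves", {
  tau <- 0.1
  piAt <- vapply(c(0.01, 0.1, 1, 10), function(g)
    dmiProbability(tau, refParams(g)), numeric(1))
  expect_true(all(diff(piAt) < 0))
  # saturation in both limits: a decade of population size shifts the
  # threshold-crossing times by < 0.05 dex (12%) at every probability
  # level, against ~0.7 dex in the intermediate regime
  onsetDex <- function(g1, g2) {
    lv <- c(1e-12, 1e-9, 1e-6, 1e-3, 0.1)
    t1 <- vapply(lv, function(l) dmiThresholdTime(refParams(g1), l),
                 numeric(1))
    t2 <- vapply(lv, function(l) dmiThresholdTime(refParams(g2), l),
                 numeric(1))
    max(abs(log10(t1 / t2)))
  }
  expect_lt(onsetDex(0.001, 0.0001), 0.05)
  expect_lt(onsetDex(100, 1000), 0.05)
  expect_gt(onsetDex(0.1, 1), 0.3)
})

test_that("threshold-crossing time solves the analytic curve and scales with mu", {
  p <- refParams(1)
  tau <- dmiThresholdTime(p, 1e-5)
  expect_equal(dmiProbability(tau / diffusionRate(p), p), 1e-5,
               tolerance = 1e-8)
  # doubling mu leaves the mu*t crossing unchanged => halves absolute time
  p2 <- refParams(1, mu = 2)
  expect_equal(dmiThresholdTime(p2, 1e-5), tau, tolerance = 1e-8)
  expect_true(is.na(suppressWarnings(
    dmiThresholdTime(p, 1e-5, tauRange = c(1e-9, 1e-8)))))
})
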