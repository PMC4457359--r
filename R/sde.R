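## Euler-Maruyama Monte Carlo of the coupled Langevin equations for two
## independent lineages, hybrid construction and empirical estimators.
##
## Time is simulated in the dimensionless variable tau = mu*t, in which the
## per-component noise variance per unit time is 1 and the only drift
## coefficient is a = 2*Ne*kappa (so a*xi0 = 1).

#' Drift of one lineage
#'
#' Drift of the pair \eqn{(x_1, x_2)} of one lineage, per unit
#' \eqn{\mu t}.  In `"full"` mode the free fitness depends on
#' \eqn{|x_1 - x_2|}, giving
#' \eqn{dx_1/d\tau = -2N_e\kappa(|x_1-x_2| - \xi_0)\,\mathrm{sign}(x_1-x_2)}
#' with the cusp at \eqn{x_1 = x_2} resolved by `sign(0) = 0`; in
#' `"linearised"` mode the single-peak quadratic gives
#' \eqn{dx_1/d\tau = -2N_e\kappa(x_1 - x_2 - \xi_0)}.  In both modes the
#' drift on \eqn{x_2} is the negative of that on \eqn{x_1}, so the centre
#' of mass feels no drift; the two modes agree whenever
#' \eqn{x_1 - x_2 > 0}.
#'
#' @param x1,x2 numeric vectors of coordinates (vectorised over
#'   replicates).
#' @param params a [ModelParams-class] object.
#' @param landscapeMode `"full"` or `"linearised"`.
#' @return A list with components `d1` and `d2` (drifts per unit
#'   \eqn{\mu t}; multiply by \eqn{\mu} for absolute time).
#' @export
lineageDrift <- function(x1, x2, params, landscapeMode = c("full", "linearised")) {
  landscapeMode <- match.arg(landscapeMode)
  lc <- landscapeConstants(params)
  a <- 2 * params@Ne * lc@kappa
  s <- x1 - x2
  d1 <- if (landscapeMode == "full") {
    -a * (abs(s) - lc@xi0) * sign(s)
  } else {
    -a * (s - lc@xi0)
  }
  list(d1 = d1, d2 = -d1)
}

#' One Euler-Maruyama step for one lineage
#'
#' \eqn{x \leftarrow x + \mathrm{drift}\cdot h + \sqrt{h}\, z} in
#' \eqn{\mu t} units, with `z` independent standard normals per component.
#'
#' @param x1,x2 numeric vectors of coordinates.
#' @param h step size in \eqn{\mu t} units.
#' @param z1,z2 standard normal draws (same length as `x1`).
#' @inheritParams lineageDrift
#' @return A list with updated `x1`, `x2`.
#' @export
eulerMaruyamaStep <- function(x1, x2, h, z1, z2, params,
                              landscapeMode = c("full", "linearised")) {
  stopifnot(h > 0)
  d <- lineageDrift(x1, x2, params, landscapeMode)
  sq <- sqrt(h)
  list(x1 = x1 + d$d1 * h + sq * z1, x2 = x2 + d$d2 * h + sq * z2)
}

reflectPair <- function(x1, x2, xiStar) {
  s <- x1 - x2
  over <- s > xiStar
  if (any(over)) {
    d <- s[over] - xiStar
    x1[over] <- x1[over] - d
    x2[over] <- x2[over] + d
  }
  under <- s < -xiStar
  if (any(under)) {
    d <- s[under] + xiStar
    x1[under] <- x1[under] - d
    x2[under] <- x2[under] + d
  }
  list(x1 = x1, x2 = x2)
}

#' Simulate two allopatric lineages
#'
#' Integrates the coupled Langevin equations for two lineages
#' \eqn{(x_1, x_2)} and \eqn{(x_1', x_2')} that share a common-ancestor
#' state at \eqn{t = 0} and evolve with independent noise thereafter.
#' In `"fixed_xi0"` mode the ancestor is \eqn{x_1(0) = \xi_0,
#' x_2(0) = 0}; in `"sample_equilibrium"` mode the ancestral separation is
#' drawn from the Gaussian equilibrium \eqn{N(\xi_0, \Delta\xi^2)}.
#'
#' Each interval between consecutive output times is split into
#' `ceiling(interval/dt)` equal Euler steps, so the effective step never
#' exceeds `dt` and output times are hit exactly.  Replicates are organised
#' in fixed blocks of 1000; per-block stream seeds are drawn from a master
#' stream seeded with `seed`, so enlarging `nReps` appends new blocks
#' without changing earlier replicates.
#'
#' @param params a [ModelParams-class] object.
#' @param config an [SDEConfig-class] object.
#' @return A [TrajectoryEnsemble-class] object.
#' @examples
#' p <- modelParams(10, 0.0025, 100, fstarOverKappaF = -25)
#' ens <- simulateLineages(p, sdeConfig(200, tOut = c(0.1, 1), seed = 7,
#'                                      landscapeMode = "linearised"))
#' ens
#' @export
simulateLineages <- function(params, config) {
  stopifnot(is(params, "ModelParams"), is(config, "SDEConfig"))
  validObject(config)
  lc <- landscapeConstants(params)
  dtBound <- min(0.01, 0.1 / (4 * params@Ne * lc@kappa))
  dt <- config@dt
  if (is.na(dt)) {
    dt <- dtBound
  } else if (dt > dtBound) {
    warning(sprintf(
      "dt = %g exceeds the recommended bound %g; the relaxation rate may be under-resolved",
      dt, dtBound))
  }
  times <- config@tOut
  nReps <- config@nReps
  blockSize <- 1000L
  nBlocks <- ceiling(nReps / blockSize)
  nT <- length(times)
  x1o <- matrix(NA_real_, nReps, nT)
  x2o <- matrix(NA_real_, nReps, nT)
  x1po <- matrix(NA_real_, nReps, nT)
  x2po <- matrix(NA_real_, nReps, nT)
  mode <- config@landscapeMode
  reflect <- config@boundaryMode == "reflect"
  set.seed(config@seed)
  blockSeeds <- sample.int(2147483646L, nBlocks, replace = TRUE)
  for (b in seq_len(nBlocks)) {
    set.seed(blockSeeds[b])
    rows <- ((b - 1L) * blockSize + 1L):min(b * blockSize, nReps)
    k <- length(rows)
    if (config@initMode == "fixed_xi0") {
      x1 <- rep(lc@xi0, blockSize)
    } else {
      x1 <- rnorm(blockSize, mean = lc@xi0, sd = lc@deltaXi)
    }
    x2 <- numeric(blockSize)
    x1p <- x1
    x2p <- x2
    prevT <- 0
    for (j in seq_len(nT)) {
      delta <- times[j] - prevT
      if (delta > 0) {
        nSub <- max(1L, ceiling(delta / dt - 1e-9))
        h <- delta / nSub
        sq <- sqrt(h)
        for (s in seq_len(nSub)) {
          z <- matrix(rnorm(4L * blockSize), blockSize, 4L)
          d <- lineageDrift(x1, x2, params, mode)
          x1 <- x1 + d$d1 * h + sq * z[, 1L]
          x2 <- x2 + d$d2 * h + sq * z[, 2L]
          d <- lineageDrift(x1p, x2p, params, mode)
          x1p <- x1p + d$d1 * h + sq * z[, 3L]
          x2p <- x2p + d$d2 * h + sq * z[, 4L]
          if (reflect) {
            r1 <- reflectPair(x1, x2, params@xiStar)
            x1 <- r1$x1; x2 <- r1$x2
            r2 <- reflectPair(x1p, x2p, params@xiStar)
            x1p <- r2$x1; x2p <- r2$x2
          }
        }
      }
      x1o[rows, j] <- x1[seq_len(k)]
      x2o[rows, j] <- x2[seq_len(k)]
      x1po[rows, j] <- x1p[seq_len(k)]
      x2po[rows, j] <- x2p[seq_len(k)]
      prevT <- times[j]
    }
  }
  new("TrajectoryEnsemble", times = times, x1 = x1o, x2 = x2o,
      x1p = x1po, x2p = x2po, config = config, params = params)
}

#' Hybrid binding energies of an ensemble
#'
#' Free recombination between the two loci in hybrids combines alleles
#' across lineages: \eqn{w = x_1 - x_2'} and \eqn{w' = x_1' - x_2}.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @return A list with matrices `w` and `wPrime` (replicates x times).
#' @export
hybridEnergies <- function(ensemble) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  list(w = ensemble@x1 - ensemble@x2p, wPrime = ensemble@x1p - ensemble@x2)
}

#' Empirical hybrid moments of an ensemble
#'
#' Per output time: the mean hybrid binding energy, the variance
#' \eqn{\hat\Sigma_{11}}, the cross-hybrid covariance
#' \eqn{\hat\Sigma_{12}}, and the mean hybrid log fitness
#' \eqn{-\kappa_F \langle w^2\rangle/2}, each with a Monte-Carlo standard
#' error (normal-theory formulas).
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @return A `data.frame` with one row per output time.
#' @export
empiricalMoments <- function(ensemble) {
  h <- hybridEnergies(ensemble)
  n <- nrow(h$w)
  params <- ensemble@params
  oneTime <- function(j) {
    w <- h$w[, j]
    wp <- h$wPrime[, j]
    s11 <- var(w)
    s22 <- var(wp)
    s12 <- if (s11 == 0 || s22 == 0) 0 else cov(w, wp)
    w2 <- w^2
    data.frame(
      mu_t = ensemble@times[j],
      meanW = mean(w), seMeanW = sd(w) / sqrt(n),
      sigma11 = s11, seSigma11 = s11 * sqrt(2 / (n - 1)),
      sigma12 = s12, seSigma12 = sqrt((s11 * s22 + s12^2) / (n - 1)),
      meanFh = -0.5 * params@kappaF * mean(w2),
      seFh = 0.5 * params@kappaF * sd(w2) / sqrt(n))
  }
  do.call(rbind, lapply(seq_along(ensemble@times), oneTime))
}

#' @importFrom stats cov
NULL

#' Empirical incompatibility probability
#'
#' \eqn{\hat P_I(t)}: the fraction of replicates whose hybrid binding
#' energy exceeds the inviability boundary, \eqn{|w(t)| > \xi^*}
#' (instantaneous-state event).  The default `"w_only"` estimator uses one
#' hybrid per replicate, keeping the binomial standard error exact;
#' `"pooled"` averages the \eqn{w} and \eqn{w'} indicators within each
#' replicate first (same mean, different standard error, since the two
#' hybrids are dependent at long times).
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param estimator `"w_only"` or `"pooled"`.
#' @return A [PIResult-class] with `method = "sde"`.
#' @export
empiricalPI <- function(ensemble, estimator = c("w_only", "pooled")) {
  estimator <- match.arg(estimator)
  h <- hybridEnergies(ensemble)
  xs <- ensemble@params@xiStar
  n <- nrow(h$w)
  if (estimator == "w_only") {
    ind <- abs(h$w) > xs
    p <- colMeans(ind)
    se <- sqrt(p * (1 - p) / n)
  } else {
    ind <- (abs(h$w) > xs) + (abs(h$wPrime) > xs)
    ind <- ind / 2
    p <- colMeans(ind)
    se <- apply(ind, 2L, sd) / sqrt(n)
  }
  PIResult(times = ensemble@times, pi = p, method = "sde", mcSE = se,
           nReps = n)
}
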