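## Closed-form solution of the linearised two-lineage dynamics and the
## resulting hybrid moments, hybrid fitness and incompatibility probability.

#' Propagator of the linearised two-locus dynamics
#'
#' The deterministic part of the linearised Langevin pair relaxes the
#' separation \eqn{x_1 - x_2} at rate \eqn{4 N_e \kappa \mu} while leaving
#' the centre of mass free; its matrix exponential is
#' \deqn{J(t) = \frac12\begin{pmatrix} 1+e^{-4N_e\kappa\mu t} &
#'   1-e^{-4N_e\kappa\mu t} \\ 1-e^{-4N_e\kappa\mu t} &
#'   1+e^{-4N_e\kappa\mu t}\end{pmatrix}.}
#' Rows sum to one for every \eqn{t}.
#'
#' @param t time (absolute units; multiply by `mu` for \eqn{\mu t}).
#' @param params a [ModelParams-class] object.
#' @return A 2x2 numeric matrix.
#' @export
propagatorJ <- function(t, params) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  stopifnot(length(t) == 1L)
  lc <- landscapeConstants(params)
  e <- exp(-4 * params@Ne * lc@kappa * params@mu * t)
  matrix(0.5 * c(1 + e, 1 - e, 1 - e, 1 + e), 2L, 2L)
}

#' Mean solution of the linearised dynamics
#'
#' \eqn{\langle x(t)\rangle = J(t) x(0) + \frac{1}{4N_e\kappa}
#' (1 - e^{-4N_e\kappa\mu t}) (1, -1)^T}: the expected separation
#' \eqn{\langle x_1 - x_2 \rangle} relaxes to \eqn{\xi_0} at rate
#' \eqn{4 N_e \kappa \mu} while the mean centre of mass stays put.
#'
#' @param t time (absolute units).
#' @param x0 numeric length-2 initial state \eqn{(x_1(0), x_2(0))}.
#' @param params a [ModelParams-class] object.
#' @return Numeric length-2 vector of expected coordinates.
#' @export
meanSolution <- function(t, x0, params) {
  stopifnot(length(x0) == 2L)
  lc <- landscapeConstants(params)
  e <- exp(-4 * params@Ne * lc@kappa * params@mu * t)
  drop(propagatorJ(t, params) %*% x0) +
    (1 / (4 * params@Ne * lc@kappa)) * (1 - e) * c(1, -1)
}

#' Mean hybrid binding energy
#'
#' With the common ancestor at the free-fitness maximum
#' (\eqn{\xi(0) = \xi_0}), the mean of each hybrid binding energy
#' \eqn{w = x_1 - x_2'} is constant in time and equal to
#' \eqn{\xi_0 = 1/(2\kappa N_e)}.
#'
#' @param t numeric times (any length; the value is constant).
#' @param params a [ModelParams-class] object.
#' @return Numeric vector of \eqn{\langle w \rangle} values.
#' @export
hybridMean <- function(t, params) {
  rep_len(landscapeConstants(params)@xi0, length(t))
}

#' Hybrid covariance of the two hybrid binding energies
#'
#' Closed-form second moments of \eqn{(w, w')}:
#' \deqn{\Sigma_{11} = \mu t + \frac{1}{8N_e\kappa}
#'   \left(1 - e^{-8N_e\kappa\mu t}\right), \qquad
#'   \Sigma_{12} = -\mu t + \frac{1}{8N_e\kappa}
#'   \left(1 - e^{-8N_e\kappa\mu t}\right).}
#' At short times \eqn{\Sigma_{11} \approx 2\mu t} (inter- plus
#' intra-lineage diffusion) and the hybrids are uncorrelated; at long times
#' (\eqn{8N_e\kappa\mu t \gg 1}) the landscape constraint makes them
#' anti-correlated.
#'
#' @param t numeric times (absolute units), \eqn{t \ge 0}.
#' @param params a [ModelParams-class] object.
#' @return A `data.frame` with columns `t`, `meanW`, `sigma11`, `sigma12`.
#' @export
hybridCovariance <- function(t, params) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  lc <- landscapeConstants(params)
  a8 <- 8 * params@Ne * lc@kappa
  mut <- params@mu * t
  sat <- -expm1(-a8 * mut) / a8
  data.frame(t = t, meanW = lc@xi0, sigma11 = mut + sat, sigma12 = -mut + sat)
}

#' Mean hybrid log fitness
#'
#' \eqn{\langle F_h(t)\rangle = F_h(0) - \mu\kappa_F t/2 -
#' \frac{\kappa_F}{16 N_e \kappa}(1 - e^{-8N_e\kappa\mu t})}, which equals
#' \eqn{-\kappa_F \langle w^2 \rangle / 2} built from [hybridMean()] and
#' [hybridCovariance()].  At short times the decay is linear with slope
#' \eqn{-\mu \kappa_F}; once the intra-lineage term saturates the slope is
#' \eqn{-\mu\kappa_F/2}.
#'
#' @param t numeric times (absolute units).
#' @param params a [ModelParams-class] object.
#' @param Fh0 initial hybrid log fitness; defaults to
#'   \eqn{-\kappa_F \xi_0^2/2}, the fitness of the common ancestor at the
#'   free-fitness maximum.
#' @return Numeric vector of mean hybrid fitness values.
#' @export
hybridFitnessMean <- function(t, params, Fh0 = NULL) {
  lc <- landscapeConstants(params)
  if (is.null(Fh0)) Fh0 <- -0.5 * params@kappaF * lc@xi0^2
  a8 <- 8 * params@Ne * lc@kappa
  mut <- params@mu * t
  Fh0 - 0.5 * params@kappaF * mut -
    (params@kappaF / (2 * a8)) * (-expm1(-a8 * mut))
}

#' Probability of a Dobzhansky-Muller incompatibility
#'
#' The probability that a hybrid binding energy \eqn{w(t)} (Gaussian with
#' mean \eqn{\langle w\rangle = \xi_0} and variance \eqn{\Sigma_{11}(t)})
#' lies beyond the inviability boundary:
#' \deqn{P_I(t) = \tfrac12\,\mathrm{erfc}\!\left(
#'   \frac{\xi^* - \langle w\rangle}{\sqrt{2\Sigma_{11}}}\right) +
#'   \tfrac12\,\mathrm{erfc}\!\left(
#'   \frac{\xi^* + \langle w\rangle}{\sqrt{2\Sigma_{11}}}\right).}
#' The complementary error function is evaluated through the Gaussian tail
#' (`pnorm(..., lower.tail = FALSE)`), accurate far into the tail.  At
#' \eqn{t = 0} the Gaussian is degenerate and the closed-form limit is the
#' indicator of \eqn{|\xi_0| > \xi^*} (zero for any viable ancestor).
#'
#' @param t numeric times (absolute units), \eqn{t \ge 0}.
#' @param params a [ModelParams-class] object.
#' @return Numeric vector of probabilities.
#' @examples
#' p <- modelParams(10, 0.0025, 100, fstarOverKappaF = -25)
#' dmiProbability(c(0, 1, 10), p)
#' @export
dmiProbability <- function(t, params) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  hm <- hybridCovariance(t, params)
  w <- hm$meanW
  s11 <- hm$sigma11
  xs <- params@xiStar
  out <- numeric(length(t))
  zero <- s11 <= 0
  out[zero] <- as.numeric(abs(w[zero]) > xs)
  if (any(!zero)) {
    sdv <- sqrt(s11[!zero])
    out[!zero] <- pnorm((xs - w[!zero]) / sdv, lower.tail = FALSE) +
      pnorm((xs + w[!zero]) / sdv, lower.tail = FALSE)
  }
  pmin(out, 1)
}

#' Analytic incompatibility curve on a log-spaced time grid
#'
#' Convenience wrapper evaluating [dmiProbability()] on a log-spaced grid
#' of \eqn{\mu t}.
#'
#' @param params a [ModelParams-class] object.
#' @param tauMin,tauMax grid limits in \eqn{\mu t} units.
#' @param n number of grid points.
#' @return A [PIResult-class] with `method = "analytic"`.
#' @export
analyticPI <- function(params, tauMin = 1e-4, tauMax = 1e3, n = 200L) {
  tau <- exp(seq(log(tauMin), log(tauMax), length.out = n))
  PIResult(times = tau, pi = dmiProbability(tau / params@mu, params),
           method = "analytic")
}

#' Curvature of log P_I against log t
#'
#' Second differences of \eqn{\log P_I} with respect to \eqn{\log t}
#' (nonuniform-grid formula).  The short-time incompatibility law behaves
#' like \eqn{\mathrm{erfc}(c/\sqrt{t})}, which has an essential singularity
#' at \eqn{t = 0}: on a log-log plot it can never look like a power law and
#' its curvature is strictly negative.  Points with \eqn{P_I \le 0} are
#' excluded.
#'
#' @param times numeric, positive times.
#' @param pi numeric, the \eqn{P_I} values (same length), or a
#'   [PIResult-class] in place of `times`.
#' @return Numeric vector of curvature values (length `n - 2` after
#'   exclusion of nonpositive points).
#' @export
logLogCurvature <- function(times, pi = NULL) {
  if (is(times, "PIResult")) {
    pi <- times@pi
    times <- times@times
  }
  keep <- pi > 0 & times > 0
  x <- log(times[keep])
  y <- log(pi[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 strictly positive points")
  i <- 2:(n - 1L)
  fwd <- (y[i + 1L] - y[i]) / (x[i + 1L] - x[i])
  bwd <- (y[i] - y[i - 1L]) / (x[i] - x[i - 1L])
  2 * (fwd - bwd) / (x[i + 1L] - x[i - 1L])
}

#' Expected number of incompatibilities and the speciation threshold
#'
#' With \eqn{M} pairwise interacting locus pairs in a genome, one DMI is
#' expected (and reproductive isolation likely) when the per-pair
#' incompatibility probability reaches \eqn{P_I \sim 1/M}.
#'
#' @param M number of pairwise interacting locus pairs.
#' @return The threshold per-pair probability \eqn{1/M}.
#' @examples
#' speciationThreshold(1e5)  # 1e-5
#' @export
speciationThreshold <- function(M) {
  stopifnot(M > 0)
  1 / M
}

#' Time at which the analytic incompatibility probability reaches a
#' threshold
#'
#' Solves \eqn{P_I(t) = } `threshold` by bisection in \eqn{\log t} on the
#' analytic curve (which is nondecreasing in \eqn{t}).
#'
#' @param params a [ModelParams-class] object.
#' @param threshold target probability (default the speciation threshold
#'   for \eqn{M = 10^5} interacting pairs).
#' @param tauRange search interval in \eqn{\mu t} units.
#' @return Time in \eqn{\mu t} units, or `NA` (with a warning) if the
#'   threshold is not bracketed on the interval.
#' @export
dmiThresholdTime <- function(params, threshold = 1e-5,
                             tauRange = c(1e-10, 1e6)) {
  f <- function(lt) dmiProbability(exp(lt) / params@mu, params) - threshold
  lo <- log(tauRange[1L]); hi <- log(tauRange[2L])
  if (f(lo) > 0 || f(hi) < 0) {
    warning("threshold not bracketed on 'tauRange'")
    return(NA_real_)
  }
  exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
}
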