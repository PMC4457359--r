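## Genotype-phenotype landscape: fitness, sequence entropy, free fitness,
## equilibrium density and probability flux.

#' Derived landscape constants
#'
#' Computes, from a [ModelParams-class] object, the total free-fitness
#' curvature \eqn{\kappa = \kappa_F + 1/(\ell N_e)}, the free-fitness
#' maximum \eqn{\xi_0 = 1/(2 \kappa N_e)}, the equilibrium width
#' \eqn{\Delta\xi = 1/\sqrt{4 \kappa N_e}}, and the relaxation rate
#' \eqn{2 N_e \kappa \mu}.  \eqn{\kappa} sums the curvature of the fitness
#' landscape and that of the (quadratic) sequence-entropy potential; their
#' balance places the most probable binding energy \eqn{\xi_0} between 0
#' (selection dominated, large \eqn{N_e}) and \eqn{\ell/2} (entropy
#' dominated, small \eqn{N_e}).
#'
#' @param params a [ModelParams-class] object.
#' @return A [LandscapeConstants-class] object.
#' @examples
#' landscapeConstants(modelParams(10, 1, 100, fstarOverKappaF = -25))
#' @export
landscapeConstants <- function(params) {
  stopifnot(is(params, "ModelParams"))
  kappa <- params@kappaF + 1 / (params@ell * params@Ne)
  new("LandscapeConstants",
      kappa = kappa,
      xi0 = 1 / (2 * kappa * params@Ne),
      deltaXi = 1 / sqrt(4 * kappa * params@Ne),
      relaxRate = 2 * params@Ne * kappa * params@mu)
}

#' Truncated quadratic log fitness of a binding energy
#'
#' \eqn{F(\xi) = -\kappa_F \xi^2 / 2} for \eqn{|\xi| \le \xi^*} and
#' \eqn{-\infty} beyond: past the inviability boundary, non-specific
#' binding outcompetes binding to the target site and the organism is
#' inviable.  The function acts on \eqn{|\xi|}; `-Inf` is an ordinary IEEE
#' value here and propagates through `exp()` as probability zero.
#'
#' @param xi numeric vector of binding energies.
#' @param params a [ModelParams-class] object.
#' @return Numeric vector of log fitness values.
#' @examples
#' p <- modelParams(10, 1, 100, fstarOverKappaF = -25)
#' bindingFitness(sqrt(50), p)   # -25, the threshold fitness
#' bindingFitness(0, p)          # 0 at the optimum
#' @export
bindingFitness <- function(xi, params) {
  stopifnot(is(params, "ModelParams"))
  f <- -0.5 * params@kappaF * xi^2
  f[abs(xi) > params@xiStar] <- -Inf
  f
}

#' Discrete sequence entropy of a mismatch class
#'
#' The number of sequence pairs at mismatch count \eqn{r} is proportional
#' to \eqn{\binom{\ell}{r}} (the number of ways of placing the mismatches),
#' so \eqn{S(r) = \ln \binom{\ell}{r}}, computed stably through
#' log-gamma.
#'
#' @param r integer mismatch counts, \eqn{0 \le r \le \ell}.
#' @param ell interface length.
#' @return Numeric vector of entropies (nats).
#' @examples
#' sequenceEntropyDiscrete(5, 10)  # log(252)
#' @export
sequenceEntropyDiscrete <- function(r, ell) {
  if (any(r < 0 | r > ell | r != round(r)))
    stop("'r' must be integers in [0, ell]")
  lchoose(ell, r)
}

#' Continuous (Stirling) sequence entropy
#'
#' Quadratic approximation \eqn{S(\xi) = -(2/\ell)(\xi - \ell/2)^2} to the
#' log binomial coefficient, maximal at \eqn{\xi = \ell/2} where matches
#' and mismatches are equally likely.  The additive constant is dropped:
#' only entropy gradients enter the dynamics and densities are normalised
#' numerically.
#'
#' @param xi numeric binding energies (mismatch scale).
#' @param ell interface length.
#' @return Numeric vector of entropies (nats, up to a constant).
#' @export
sequenceEntropyContinuous <- function(xi, ell) {
  -(2 / ell) * (xi - ell / 2)^2
}

#' Free fitness of a binding energy
#'
#' \eqn{\Phi(\xi) = F(\xi) + S(\xi)/(4 N_e)} with the continuous entropy.
#' On \eqn{|\xi| \le \xi^*} this is exactly
#' \eqn{-\kappa(\xi - \xi_0)^2/2} plus a constant (quadratic completion),
#' with \eqn{\kappa} and \eqn{\xi_0} as in [landscapeConstants()]; beyond
#' the boundary it is \eqn{-\infty}.
#'
#' @param xi numeric vector of binding energies.
#' @param params a [ModelParams-class] object.
#' @return Numeric vector of free fitness values.
#' @export
freeFitness <- function(xi, params) {
  stopifnot(is(params, "ModelParams"))
  bindingFitness(xi, params) +
    sequenceEntropyContinuous(xi, params@ell) / (4 * params@Ne)
}

#' Analytic free-fitness gradient
#'
#' \eqn{d\Phi/d\xi = -\kappa(\xi - \xi_0)} on the viable domain — exact,
#' because both the fitness and the continuous entropy are quadratic.
#'
#' @inheritParams freeFitness
#' @return Numeric vector of gradients.
#' @export
freeFitnessGradient <- function(xi, params) {
  lc <- landscapeConstants(params)
  -lc@kappa * (xi - lc@xi0)
}

#' Equilibrium phenotype density
#'
#' The stationary law of the origin-fixation dynamics,
#' \eqn{p(\xi) \propto e^{4 N_e \Phi(\xi)}}.
#'
#' With `domain = "unbounded"` the linearised (quadratic-completed)
#' landscape is used on the whole line and the density is exactly Gaussian
#' with mean \eqn{\xi_0} and variance \eqn{1/(4 N_e \kappa)}; this is the
#' form entering the closed-form hybrid theory.  With
#' `domain = "truncated"` the density is evaluated on \eqn{[0, \xi^*]}
#' (binding energy as a magnitude, hard inviability wall) and normalised
#' numerically by the trapezoid rule.
#'
#' @param params a [ModelParams-class] object.
#' @param domain `"unbounded"` or `"truncated"`.
#' @param n number of grid points.
#' @param widthFactor half-width of the unbounded grid in units of
#'   \eqn{\Delta\xi}.
#' @return A `data.frame` with columns `xi` and `p` (density on the grid).
#' @examples
#' d <- equilibriumDensity(modelParams(10, 1, 100, fstarOverKappaF = -25))
#' sum(d$p) * diff(d$xi[1:2])  # ~ 1
#' @export
equilibriumDensity <- function(params, domain = c("unbounded", "truncated"),
                               n = 1024L, widthFactor = 8) {
  stopifnot(is(params, "ModelParams"))
  domain <- match.arg(domain)
  lc <- landscapeConstants(params)
  if (lc@kappa <= 0) stop("non-integrable landscape: kappa <= 0")
  if (domain == "unbounded") {
    xi <- seq(lc@xi0 - widthFactor * lc@deltaXi,
              lc@xi0 + widthFactor * lc@deltaXi, length.out = n)
    p <- dnorm(xi, mean = lc@xi0, sd = lc@deltaXi)
  } else {
    xi <- seq(0, params@xiStar, length.out = n)
    logp <- 4 * params@Ne * freeFitness(xi, params)
    logp <- logp - max(logp)
    p <- exp(logp)
    h <- xi[2L] - xi[1L]
    z <- h * (sum(p) - 0.5 * (p[1L] + p[n]))
    p <- p / z
  }
  data.frame(xi = xi, p = p)
}

#' Probability flux in phenotype space
#'
#' \eqn{J(\xi) = -\mu p'(\xi)/2 + 2 N_e \mu\, p(\xi)\, \Phi'(\xi)}: the
#' diffusive flux plus the response to the free-fitness gradient with the
#' evolutionary Einstein relation \eqn{1/\zeta = 2 N_e \mu} substituted.
#' At the stationary density the two terms cancel identically.
#'
#' `p` is differentiated by central differences on the (uniform) grid
#' (one-sided at the ends); the free-fitness gradient is evaluated in
#' closed form.
#'
#' @param p numeric vector of density values on `xi`.
#' @param xi uniform grid of binding energies (length >= 3).
#' @param params a [ModelParams-class] object.
#' @return Numeric vector of fluxes on the grid.
#' @export
probabilityFlux <- function(p, xi, params) {
  stopifnot(is(params, "ModelParams"))
  n <- length(xi)
  if (n < 3L || length(p) != n)
    stop("'xi' and 'p' must have equal length >= 3")
  h <- diff(xi)
  if (max(abs(h - h[1L])) > 1e-8 * abs(h[1L]))
    stop("'xi' must be a uniform grid")
  h <- h[1L]
  dp <- numeric(n)
  dp[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / (2 * h)
  dp[1L] <- (p[2L] - p[1L]) / h
  dp[n] <- (p[n] - p[n - 1L]) / h
  mu <- params@mu
  -0.5 * mu * dp + 2 * params@Ne * mu * p * freeFitnessGradient(xi, params)
}
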