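## S4 classes for the model parameterisation and the simulation products.

#' Model parameters for the TF-TFBS coevolution landscape
#'
#' Bundles the full parameterisation of the coarse-grained model: the
#' effective interface length \eqn{\ell} (number of interacting
#' positions), the fitness curvature \eqn{\kappa_F}, the effective
#' population size \eqn{N_e}, the per-component phenotypic diffusion rate
#' \eqn{\mu}, the inviability boundary \eqn{\xi^*}, the energy-per-mismatch
#' scale \eqn{\epsilon}, and (for the discrete simulator only) the per-site
#' mutation rate \eqn{\mu_0}.
#'
#' @slot ell integer, interface length \eqn{\ell \ge 1} (sites).
#' @slot kappaF numeric, fitness curvature \eqn{\kappa_F \ge 0} (per
#'   binding-energy squared).
#' @slot Ne numeric, effective population size \eqn{N_e \ge 1}.
#' @slot mu numeric, per-component diffusion rate \eqn{\mu > 0} (per unit
#'   time); the noise of each Langevin component has
#'   \eqn{\langle\eta_i\eta_j\rangle = \mu \delta_{ij}\delta(t-t')}.
#' @slot xiStar numeric, inviability boundary \eqn{\xi^* > 0}
#'   (binding-energy units).
#' @slot epsilon numeric, binding energy per mismatch \eqn{\epsilon > 0};
#'   default 1 so that \eqn{\xi} is directly the mismatch count.
#' @slot mu0 numeric, optional per-site mutation rate used by the discrete
#'   module (`NA` when unused).
#'
#' @seealso [modelParams()] for the user-facing constructor,
#'   [landscapeConstants()] for derived quantities.
#' @export
setClass("ModelParams",
  representation(
    ell = "integer",
    kappaF = "numeric",
    Ne = "numeric",
    mu = "numeric",
    xiStar = "numeric",
    epsilon = "numeric",
    mu0 = "numeric"
  ),
  prototype(
    ell = 10L, kappaF = 1, Ne = 100, mu = 1, xiStar = sqrt(50),
    epsilon = 1, mu0 = NA_real_
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  if (length(object@ell) != 1L || is.na(object@ell) || object@ell < 1L)
    msg <- c(msg, "'ell' must be a single integer >= 1")
  if (length(object@kappaF) != 1L || is.na(object@kappaF) || object@kappaF < 0)
    msg <- c(msg, "'kappaF' must be a single nonnegative number")
  if (length(object@Ne) != 1L || is.na(object@Ne) || object@Ne < 1)
    msg <- c(msg, "'Ne' must be a single number >= 1")
  if (length(object@mu) != 1L || is.na(object@mu) || object@mu <= 0)
    msg <- c(msg, "'mu' must be a single positive number")
  if (length(object@xiStar) != 1L || is.na(object@xiStar) || object@xiStar <= 0)
    msg <- c(msg, "'xiStar' must be a single positive number")
  if (length(object@epsilon) != 1L || is.na(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be a single positive number")
  if (length(object@mu0) != 1L || (!is.na(object@mu0) && object@mu0 <= 0))
    msg <- c(msg, "'mu0', when given, must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelParams object
#'
#' The inviability boundary may be given directly as `xiStar` or through
#' the fitness-threshold ratio `fstarOverKappaF` \eqn{= F^*/\kappa_F}
#' (necessarily negative), in which case
#' \eqn{\xi^* = \sqrt{-2 F^*/\kappa_F}} by inversion of the quadratic log
#' fitness at the threshold.  Exactly one of the two must be supplied.
#'
#' When `mu0` is supplied, the weak-mutation diagnostic
#' \eqn{n \mu_0 N_e} with \eqn{n = 2\ell} (total number of mutable sites in
#' the interacting pair) is computed; values at or above 0.1 trigger a
#' warning because the origin-fixation (monomorphic) picture then starts to
#' break down.
#'
#' @param ell interface length (positive integer).
#' @param kappaF fitness curvature (nonnegative).
#' @param Ne effective population size (>= 1).
#' @param mu per-component diffusion rate (positive); defaults to 1 so that
#'   time is measured in units of \eqn{\mu t}.
#' @param xiStar inviability boundary (positive), or `NULL`.
#' @param fstarOverKappaF threshold ratio \eqn{F^*/\kappa_F} (negative), or
#'   `NULL`.
#' @param epsilon binding energy per mismatch (positive), default 1.
#' @param mu0 optional per-site mutation rate for the discrete module.
#' @return A [ModelParams-class] object.
#' @examples
#' p <- modelParams(ell = 10, kappaF = 1, Ne = 100, fstarOverKappaF = -25)
#' xiStar(p)        # sqrt(50) ~ 7.07
#' landscapeConstants(p)
#' @export
modelParams <- function(ell, kappaF, Ne, mu = 1, xiStar = NULL,
                        fstarOverKappaF = NULL, epsilon = 1,
                        mu0 = NA_real_) {
  if (is.null(xiStar) == is.null(fstarOverKappaF))
    stop("supply exactly one of 'xiStar' and 'fstarOverKappaF'")
  if (is.null(xiStar)) {
    if (fstarOverKappaF >= 0)
      stop("'fstarOverKappaF' must be negative")
    xiStar <- sqrt(-2 * fstarOverKappaF)
  }
  obj <- new("ModelParams", ell = as.integer(ell), kappaF = as.numeric(kappaF),
             Ne = as.numeric(Ne), mu = as.numeric(mu),
             xiStar = as.numeric(xiStar), epsilon = as.numeric(epsilon),
             mu0 = as.numeric(mu0))
  if (!is.na(obj@mu0)) {
    diag <- 2 * obj@ell * obj@mu0 * obj@Ne
    if (diag >= 0.1)
      warning(sprintf(
        "weak-mutation diagnostic 2*ell*mu0*Ne = %.3g >= 0.1: the monomorphic (origin-fixation) approximation may be poor",
        diag))
  }
  obj
}

#' Derived constants of the free fitness landscape
#'
#' Holds the quantities derived from a [ModelParams-class] object: the total
#' free-fitness curvature \eqn{\kappa = \kappa_F + 1/(\ell N_e)}, the
#' free-fitness maximum \eqn{\xi_0 = 1/(2\kappa N_e)}, the equilibrium width
#' \eqn{\Delta\xi = 1/\sqrt{4\kappa N_e}}, and the characteristic relaxation
#' rate \eqn{2 N_e \kappa \mu}.
#'
#' @slot kappa numeric, total curvature.
#' @slot xi0 numeric, most probable binding energy at equilibrium.
#' @slot deltaXi numeric, equilibrium width (standard deviation).
#' @slot relaxRate numeric, relaxation rate of the mean phenotype.
#' @seealso [landscapeConstants()]
#' @export
setClass("LandscapeConstants",
  representation(kappa = "numeric", xi0 = "numeric", deltaXi = "numeric",
                 relaxRate = "numeric"))

#' Configuration of the Langevin Monte-Carlo simulator
#'
#' @slot nReps integer, number of replicate lineage pairs.
#' @slot dt numeric, Euler-Maruyama step in \eqn{\mu t} units (`NA` means
#'   choose the default `min(0.01, 0.1/(4*Ne*kappa))` at simulation time).
#' @slot tOut numeric, increasing output times in \eqn{\mu t} units.
#' @slot seed integer, root seed.
#' @slot landscapeMode `"full"` (cusped landscape in \eqn{|x_1-x_2|}) or
#'   `"linearised"` (single-peak quadratic).
#' @slot boundaryMode `"none"` or `"reflect"` (reflect \eqn{x_1-x_2} at
#'   \eqn{\pm\xi^*}).
#' @slot initMode `"fixed_xi0"` (ancestor at the free-fitness maximum) or
#'   `"sample_equilibrium"` (ancestor drawn from the Gaussian equilibrium).
#' @seealso [sdeConfig()], [simulateLineages()]
#' @export
setClass("SDEConfig",
  representation(
    nReps = "integer", dt = "numeric", tOut = "numeric", seed = "integer",
    landscapeMode = "character", boundaryMode = "character",
    initMode = "character"
  ))

setValidity("SDEConfig", function(object) {
  msg <- character()
  if (object@nReps < 1L) msg <- c(msg, "'nReps' must be >= 1")
  if (!is.na(object@dt) && object@dt <= 0)
    msg <- c(msg, "'dt' must be positive (or NA for the default)")
  if (length(object@tOut) < 1L || any(object@tOut < 0) ||
      is.unsorted(object@tOut, strictly = TRUE))
    msg <- c(msg, "'tOut' must be strictly increasing and nonnegative")
  if (!object@landscapeMode %in% c("full", "linearised"))
    msg <- c(msg, "'landscapeMode' must be 'full' or 'linearised'")
  if (!object@boundaryMode %in% c("none", "reflect"))
    msg <- c(msg, "'boundaryMode' must be 'none' or 'reflect'")
  if (!object@initMode %in% c("fixed_xi0", "sample_equilibrium"))
    msg <- c(msg, "'initMode' must be 'fixed_xi0' or 'sample_equilibrium'")
  if (length(msg)) msg else TRUE
})

#' Construct an SDEConfig
#'
#' @param nReps replicate count.
#' @param tOut increasing output times (\eqn{\mu t} units).
#' @param seed integer root seed.
#' @param dt Euler step in \eqn{\mu t} units; `NA` (default) selects
#'   `min(0.01, 0.1/(4*Ne*kappa))` when the simulation is run, which
#'   resolves the relaxation rate uniformly across population sizes.
#' @param landscapeMode `"full"` or `"linearised"`.
#' @param boundaryMode `"none"` or `"reflect"`.
#' @param initMode `"fixed_xi0"` or `"sample_equilibrium"`.
#' @return An [SDEConfig-class] object.
#' @export
sdeConfig <- function(nReps, tOut, seed = 1L, dt = NA_real_,
                      landscapeMode = c("full", "linearised"),
                      boundaryMode = c("none", "reflect"),
                      initMode = c("fixed_xi0", "sample_equilibrium")) {
  new("SDEConfig", nReps = as.integer(nReps), dt = as.numeric(dt),
      tOut = as.numeric(tOut), seed = as.integer(seed),
      landscapeMode = match.arg(landscapeMode),
      boundaryMode = match.arg(boundaryMode),
      initMode = match.arg(initMode))
}

#' Monte-Carlo ensemble of lineage trajectories
#'
#' Rows index replicates, columns index output times.  `x1`, `x2` are the
#' TF- and TFBS-like coordinates of the first lineage; `x1p`, `x2p` of the
#' second.  The two lineages share their initial state (common ancestor)
#' and thereafter evolve with independent noise.
#'
#' @slot times numeric, output times in \eqn{\mu t} units.
#' @slot x1,x2,x1p,x2p numeric matrices (replicates x times).
#' @slot config the [SDEConfig-class] used.
#' @slot params the [ModelParams-class] used.
#' @seealso [simulateLineages()], [hybridEnergies()], [empiricalPI()]
#' @export
setClass("TrajectoryEnsemble",
  representation(
    times = "numeric", x1 = "matrix", x2 = "matrix",
    x1p = "matrix", x2p = "matrix",
    config = "SDEConfig", params = "ModelParams"
  ))

setValidity("TrajectoryEnsemble", function(object) {
  dims <- vapply(list(object@x1, object@x2, object@x1p, object@x2p),
                 function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    return("trajectory matrices must share dimensions")
  if (ncol(object@x1) != length(object@times))
    return("number of columns must match length(times)")
  TRUE
})

#' Incompatibility-probability curve
#'
#' @slot times numeric, times in \eqn{\mu t} units.
#' @slot pi numeric, \eqn{P_I(t)} values in `[0, 1]`.
#' @slot method `"analytic"`, `"sde"` or `"discrete"`.
#' @slot mcSE numeric, per-time Monte-Carlo standard errors (`NA` for the
#'   analytic method).
#' @slot nReps integer, replicate count behind a Monte-Carlo estimate
#'   (`NA` for analytic).
#' @seealso [dmiProbability()], [empiricalPI()], [gillespieTwoLineages()]
#' @export
setClass("PIResult",
  representation(times = "numeric", pi = "numeric", method = "character",
                 mcSE = "numeric", nReps = "integer"))

setValidity("PIResult", function(object) {
  msg <- character()
  if (length(object@pi) != length(object@times))
    msg <- c(msg, "'pi' and 'times' must have equal length")
  if (any(object@pi < -1e-12 | object@pi > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "'pi' values must lie in [0, 1]")
  if (!object@method %in% c("analytic", "sde", "discrete"))
    msg <- c(msg, "'method' must be analytic, sde or discrete")
  if (length(msg)) msg else TRUE
})

PIResult <- function(times, pi, method, mcSE = NA_real_, nReps = NA_integer_) {
  new("PIResult", times = as.numeric(times), pi = as.numeric(pi),
      method = method,
      mcSE = rep_len(as.numeric(mcSE), length(times)),
      nReps = as.integer(nReps))
}

#' Master-equation rate matrix on mismatch count
#'
#' Tridiagonal generator of the origin-fixation birth-death chain on the
#' mismatch count \eqn{r \in \{0, ..., \ell\}}.  Transitions into inviable
#' states \eqn{r > r^*} have rate zero (an inviable mutant never fixes).
#'
#' @slot Q numeric matrix, \eqn{(\ell+1)\times(\ell+1)} generator (rows sum
#'   to zero).
#' @slot nu numeric, the selection-scaling constant of the fixation law
#'   (\eqn{4N_e} or \eqn{2(2N_e-1)}).
#' @slot rStar integer, inviability boundary on mismatch count,
#'   \eqn{r^* = \lfloor \xi^*/\epsilon \rfloor}.
#' @slot fixationMode `"diffusion"` or `"wf_exact"`.
#' @slot params the [ModelParams-class] used.
#' @seealso [buildRateMatrix()], [stationaryDistribution()],
#'   [boltzmannStationary()]
#' @export
setClass("RateMatrix",
  representation(Q = "matrix", nu = "numeric", rStar = "integer",
                 fixationMode = "character", params = "ModelParams"))

setValidity("RateMatrix", function(object) {
  Q <- object@Q
  if (nrow(Q) != ncol(Q)) return("'Q' must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) return("off-diagonal rates must be nonnegative")
  if (max(abs(rowSums(Q))) > 1e-8 * max(1, max(abs(Q))))
    return("rows of 'Q' must sum to zero")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ModelParams", function(object) {
  lc <- landscapeConstants(object)
  cat("ModelParams\n")
  cat(sprintf("  ell = %d, kappaF = %g, Ne = %g, mu = %g\n",
              object@ell, object@kappaF, object@Ne, object@mu))
  cat(sprintf("  xiStar = %g, epsilon = %g, mu0 = %s\n", object@xiStar,
              object@epsilon,
              if (is.na(object@mu0)) "NA" else format(object@mu0)))
  cat(sprintf("  derived: kappa = %g, xi0 = %g, deltaXi = %g, 4*Ne*kappaF = %g\n",
              lc@kappa, lc@xi0, lc@deltaXi,
              4 * object@Ne * object@kappaF))
})

setMethod("show", "LandscapeConstants", function(object) {
  cat("LandscapeConstants\n")
  cat(sprintf("  kappa = %g (free-fitness curvature)\n", object@kappa))
  cat(sprintf("  xi0 = %g (most probable binding energy)\n", object@xi0))
  cat(sprintf("  deltaXi = %g (equilibrium width)\n", object@deltaXi))
  cat(sprintf("  relaxRate = %g (2*Ne*kappa*mu)\n", object@relaxRate))
})

setMethod("show", "SDEConfig", function(object) {
  cat("SDEConfig\n")
  cat(sprintf("  nReps = %d, dt = %s, seed = %d\n", object@nReps,
              if (is.na(object@dt)) "auto" else format(object@dt),
              object@seed))
  cat(sprintf("  landscape = %s, boundary = %s, init = %s\n",
              object@landscapeMode, object@boundaryMode, object@initMode))
  cat(sprintf("  %d output times in [%g, %g] (mu*t units)\n",
              length(object@tOut), min(object@tOut), max(object@tOut)))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat("TrajectoryEnsemble\n")
  cat(sprintf("  %d replicates x %d output times (mu*t in [%g, %g])\n",
              nrow(object@x1), length(object@times), min(object@times),
              max(object@times)))
  cat(sprintf("  landscape = %s, seed = %d\n", object@config@landscapeMode,
              object@config@seed))
})

setMethod("show", "PIResult", function(object) {
  cat(sprintf("PIResult (%s)\n", object@method))
  cat(sprintf("  %d times in [%g, %g]; P_I in [%.3g, %.3g]\n",
              length(object@times), min(object@times), max(object@times),
              min(object@pi), max(object@pi)))
  if (!all(is.na(object@mcSE)))
    cat(sprintf("  Monte-Carlo SE attached (nReps = %d)\n", object@nReps))
})

setMethod("show", "RateMatrix", function(object) {
  cat(sprintf("RateMatrix: %d states (r = 0..%d), rStar = %d, nu = %g (%s)\n",
              nrow(object@Q), nrow(object@Q) - 1L, object@rStar, object@nu,
              object@fixationMode))
})

## ---- coercions ----------------------------------------------------------

#' @export
#' @method as.data.frame PIResult
as.data.frame.PIResult <- function(x, ...) {
  data.frame(mu_t = x@times, p_i = x@pi, se = x@mcSE, method = x@method)
}

setAs("PIResult", "data.frame", function(from) as.data.frame.PIResult(from))
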