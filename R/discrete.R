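## Discrete ground truth: binary-string origin-fixation simulation and the
## tridiagonal master-equation chain on mismatch count r.

#' Mismatch count between two binary sequences
#'
#' The Hamming-type mismatch count between the TF interface string and the
#' binding-site string; the binding energy is \eqn{\epsilon r}.  Inputs may
#' be equal-length 0/1 (or logical) vectors, or single character strings of
#' 0s and 1s such as `"1010"`.
#'
#' @param g1,g2 the two sequences.
#' @return Integer mismatch count.
#' @examples
#' mismatchCount("1010", "1001")  # 2
#' @export
mismatchCount <- function(g1, g2) {
  asBits <- function(g) {
    if (is.character(g) && length(g) == 1L)
      g <- as.integer(strsplit(g, "")[[1L]])
    as.integer(g)
  }
  b1 <- asBits(g1)
  b2 <- asBits(g2)
  if (length(b1) != length(b2)) stop("sequences must have equal length")
  sum(b1 != b2)
}

#' Fixation probability of a mutant with log-fitness difference deltaF
#'
#' A diploid origin-fixation law satisfying the detailed-balance
#' (Sella-Hirsh) condition \eqn{\pi(\Delta F)/\pi(-\Delta F) =
#' e^{\nu \Delta F}} with the mode's \eqn{\nu}, and the neutral limit
#' \eqn{\pi(0) = 1/(2N_e)}:
#' \itemize{
#'   \item `"diffusion"` (\eqn{\nu = 4N_e}):
#'     \eqn{\pi(s) = 2s / (1 - e^{-4N_e s})};
#'   \item `"wf_exact"` (\eqn{\nu = 2(2N_e - 1)}):
#'     \eqn{\pi(s) = (1 - e^{-2s}) / (1 - e^{-4N_e s})}.
#' }
#' \eqn{\pi(-\infty) = 0} (an inviable mutant never fixes) and
#' \eqn{\pi(+\infty) = 1}.  For \eqn{|\nu \Delta F|} below a switch
#' threshold the ratio is evaluated by series expansion about the neutral
#' limit.
#'
#' @param deltaF numeric vector of log-fitness differences (may contain
#'   `-Inf`/`Inf`).
#' @param Ne effective population size (>= 1).
#' @param formulaMode `"diffusion"` or `"wf_exact"`.
#' @return Numeric vector of fixation probabilities.
#' @examples
#' fixationProbability(0, 50)             # 1/(2*50)
#' fixationProbability(-Inf, 50)          # 0
#' @export
fixationProbability <- function(deltaF, Ne,
                                formulaMode = c("diffusion", "wf_exact")) {
  formulaMode <- match.arg(formulaMode)
  if (Ne < 1) stop("'Ne' must be >= 1")
  s <- as.numeric(deltaF)
  out <- numeric(length(s))
  out[s == -Inf] <- 0
  out[s == Inf] <- 1
  fin <- is.finite(s)
  if (any(fin)) {
    sf <- s[fin]
    u <- 4 * Ne * sf
    small <- abs(u) < 1e-6 & abs(sf) < 1e-6
    res <- numeric(length(sf))
    if (formulaMode == "diffusion") {
      ## pi(s) = 2s / (1 - e^{-4 Ne s});  series: (1/2Ne)(1 + u/2 + u^2/12)
      res[!small] <- 2 * sf[!small] / (-expm1(-u[!small]))
      res[small] <- (1 / (2 * Ne)) *
        (1 + u[small] / 2 + u[small]^2 / 12)
    } else {
      ## pi(s) = (1 - e^{-2s}) / (1 - e^{-4 Ne s})
      ## series: (1/2Ne)(1 - s + (2/3)s^2)(1 + u/2 + u^2/12)
      res[!small] <- expm1(-2 * sf[!small]) / expm1(-u[!small])
      res[small] <- (1 / (2 * Ne)) *
        (1 - sf[small] + (2 / 3) * sf[small]^2) *
        (1 + u[small] / 2 + u[small]^2 / 12)
    }
    out[fin] <- res
  }
  out
}

## log fitness of mismatch class r (binding energy epsilon*r), -Inf beyond
## rStar
fitnessOfR <- function(r, params, rStar) {
  f <- -0.5 * params@kappaF * (params@epsilon * r)^2
  f[r > rStar] <- -Inf
  f
}

#' Build the origin-fixation rate matrix on mismatch count
#'
#' Tridiagonal generator of the birth-death chain on
#' \eqn{r \in \{0, \dots, \ell\}}.  The mutational supply to each move is
#' \eqn{2N_e} gene copies times the per-copy mutation rate toward that
#' class: a flip of either sequence at any of the \eqn{\ell - r} matched
#' positions creates a mismatch, and at any of the \eqn{r} mismatched
#' positions removes one (binary alphabet), so
#' \deqn{k(r \to r+1) = 2N_e \cdot 2\mu_0(\ell - r)\,\pi(F(r{+}1)-F(r)),
#'   \qquad
#'   k(r \to r-1) = 2N_e \cdot 2\mu_0 r\,\pi(F(r{-}1)-F(r)).}
#' Transitions into inviable classes \eqn{r > r^*} have rate zero because
#' an inviable mutant has fixation probability zero; with the neutral
#' normalisation above the neutral substitution rate equals the mutation
#' rate and the chain's variance grows as \eqn{2\mu t} with
#' \eqn{\mu = \ell\mu_0}.
#'
#' The chain satisfies detailed balance with respect to
#' \eqn{p(r) \propto \binom{\ell}{r} e^{\nu F(r)}} truncated at \eqn{r^*}.
#'
#' @param params a [ModelParams-class] with `mu0` set.
#' @param formulaMode fixation law, see [fixationProbability()].
#' @return A [RateMatrix-class] object.
#' @export
buildRateMatrix <- function(params, formulaMode = c("diffusion", "wf_exact")) {
  stopifnot(is(params, "ModelParams"))
  formulaMode <- match.arg(formulaMode)
  if (is.na(params@mu0)) stop("'mu0' must be set for the discrete module")
  ell <- params@ell
  Ne <- params@Ne
  mu0 <- params@mu0
  rStar <- as.integer(floor(params@xiStar / params@epsilon))
  r <- 0:ell
  Fr <- fitnessOfR(r, params, rStar)
  Q <- matrix(0, ell + 1L, ell + 1L)
  for (i in seq_len(ell)) {          # i indexes state r = i - 1
    rr <- i - 1L
    dFup <- if (is.infinite(Fr[i + 1L]) && is.infinite(Fr[i])) 0
            else Fr[i + 1L] - Fr[i]
    dFdn <- if (i > 1L) {
      if (is.infinite(Fr[i - 1L]) && is.infinite(Fr[i])) 0
      else Fr[i - 1L] - Fr[i]
    } else NA_real_
    Q[i, i + 1L] <- 2 * Ne * 2 * mu0 * (ell - rr) *
      fixationProbability(dFup, Ne, formulaMode)
    if (i > 1L)
      Q[i, i - 1L] <- 2 * Ne * 2 * mu0 * rr *
        fixationProbability(dFdn, Ne, formulaMode)
  }
  ## last state r = ell: downward only
  dFdn <- if (is.infinite(Fr[ell]) && is.infinite(Fr[ell + 1L])) 0
          else Fr[ell] - Fr[ell + 1L]
  Q[ell + 1L, ell] <- 2 * Ne * 2 * mu0 * ell *
    fixationProbability(dFdn, Ne, formulaMode)
  diag(Q) <- -rowSums(Q)
  nu <- if (formulaMode == "diffusion") 4 * Ne else 2 * (2 * Ne - 1)
  new("RateMatrix", Q = Q, nu = nu, rStar = rStar,
      fixationMode = formulaMode, params = params)
}

#' Stationary distribution of a rate matrix
#'
#' Solves \eqn{Q^T p = 0}, \eqn{\sum p = 1} by least squares on the
#' recurrent (viable) block \eqn{r \le r^*}; inviable classes are
#' transient and carry zero stationary mass.  This is an independent
#' numerical route — compare with the closed-form
#' [boltzmannStationary()].
#'
#' @param x a [RateMatrix-class] object.
#' @return Numeric probability vector over \eqn{r = 0, \dots, \ell}.
#' @export
stationaryDistribution <- function(x) {
  stopifnot(is(x, "RateMatrix"))
  nState <- nrow(x@Q)
  v <- seq_len(min(x@rStar + 1L, nState))
  A <- t(x@Q[v, v, drop = FALSE])
  M <- rbind(A, rep(1, length(v)))
  b <- c(rep(0, length(v)), 1)
  p <- qr.solve(M, b)
  p[p < 0 & p > -1e-12] <- 0
  out <- numeric(nState)
  out[v] <- p / sum(p)
  out
}

#' Boltzmann stationary law on mismatch count
#'
#' The closed-form stationary distribution of the origin-fixation chain:
#' \eqn{p(r) \propto \binom{\ell}{r} e^{\nu F(r)}} for \eqn{r \le r^*}
#' and zero beyond, where \eqn{\nu} matches the fixation law
#' (\eqn{4N_e} or \eqn{2(2N_e-1)}).
#'
#' @param params a [ModelParams-class] object.
#' @param formulaMode `"diffusion"` or `"wf_exact"`.
#' @return Numeric probability vector over \eqn{r = 0, \dots, \ell}.
#' @export
boltzmannStationary <- function(params,
                                formulaMode = c("diffusion", "wf_exact")) {
  formulaMode <- match.arg(formulaMode)
  ell <- params@ell
  rStar <- as.integer(floor(params@xiStar / params@epsilon))
  nu <- if (formulaMode == "diffusion") 4 * params@Ne
        else 2 * (2 * params@Ne - 1)
  r <- 0:ell
  logw <- lchoose(ell, r) + nu * fitnessOfR(r, params, rStar)
  logw[r > rStar] <- -Inf
  w <- exp(logw - max(logw))
  w / sum(w)
}

## One lineage: continuous-time kinetic Monte Carlo on an explicit pair of
## binary strings, recording the state at the requested absolute times.
## Time unit: the same absolute time as mu0 (so mu*t = ell*mu0*t).
simulateLineageStrings <- function(b1, b2, tAbsOut, params, rStar,
                                   formulaMode) {
  ell <- params@ell
  Ne <- params@Ne
  mu0 <- params@mu0
  nOut <- length(tAbsOut)
  out1 <- matrix(NA_integer_, nOut, ell)
  out2 <- matrix(NA_integer_, nOut, ell)
  t <- 0
  idx <- 1L
  repeat {
    r <- sum(b1 != b2)
    Fr <- fitnessOfR(c(r - 1L, r, r + 1L), params, rStar)
    dFup <- if (r < ell) Fr[3L] - Fr[2L] else -Inf
    dFdn <- if (r > 0L) Fr[1L] - Fr[2L] else -Inf
    ku <- if (r < ell)
      2 * Ne * 2 * mu0 * (ell - r) *
        fixationProbability(dFup, Ne, formulaMode) else 0
    kd <- if (r > 0L)
      2 * Ne * 2 * mu0 * r *
        fixationProbability(dFdn, Ne, formulaMode) else 0
    tot <- ku + kd
    tNext <- if (tot > 0) t + rexp(1L) / tot else Inf
    while (idx <= nOut && tAbsOut[idx] < tNext) {
      out1[idx, ] <- b1
      out2[idx, ] <- b2
      idx <- idx + 1L
    }
    if (idx > nOut) break
    t <- tNext
    up <- runif(1L) < ku / tot
    eligible <- if (up) which(b1 == b2) else which(b1 != b2)
    pos <- eligible[sample.int(length(eligible), 1L)]
    if (runif(1L) < 0.5) b1[pos] <- 1L - b1[pos] else b2[pos] <- 1L - b2[pos]
  }
  list(b1 = out1, b2 = out2)
}

#' Discrete two-lineage origin-fixation simulation
#'
#' Continuous-time kinetic Monte Carlo on explicit binary string pairs for
#' two lineages sharing a common ancestor, with hybrids formed by crossing
#' alleles: hybrid mismatch counts `mismatch(g1, g2')` and
#' `mismatch(g1', g2)`.  An incompatibility is the instantaneous event
#' that the hybrid mismatch exceeds \eqn{r^* = \lfloor\xi^*/\epsilon\rfloor}.
#'
#' The ancestor is placed at the stationary mode
#' \eqn{r_0 = \mathrm{round}(\xi_0/\epsilon)} (`ancestor = "mode"`,
#' mirroring the continuous `fixed_xi0` initial condition) or drawn from
#' the Boltzmann stationary law (`ancestor = "stationary"`); the mismatch
#' positions are placed uniformly at random.  Replicates consume
#' consecutive segments of a single stream seeded once with `seed`, so
#' enlarging `nReps` appends replicates without changing earlier ones.
#'
#' @param params a [ModelParams-class] with `mu0` set.
#' @param nReps number of replicate lineage pairs.
#' @param tOut increasing output times in \eqn{\mu t} units
#'   (\eqn{\mu = \ell \mu_0}).
#' @param seed integer root seed.
#' @param ancestor `"mode"` or `"stationary"`.
#' @param formulaMode fixation law, see [fixationProbability()].
#' @return A list with components `pi` (a [PIResult-class],
#'   `method = "discrete"`), `moments` (a `data.frame` of hybrid mean and
#'   variance in binding-energy units per output time) and `hybridR`
#'   (matrix of hybrid mismatch counts, replicates x times).
#' @export
gillespieTwoLineages <- function(params, nReps, tOut, seed = 1L,
                                 ancestor = c("mode", "stationary"),
                                 formulaMode = c("diffusion", "wf_exact")) {
  stopifnot(is(params, "ModelParams"))
  ancestor <- match.arg(ancestor)
  formulaMode <- match.arg(formulaMode)
  if (is.na(params@mu0)) stop("'mu0' must be set for the discrete module")
  ell <- params@ell
  rStar <- as.integer(floor(params@xiStar / params@epsilon))
  lc <- landscapeConstants(params)
  mu <- ell * params@mu0           # per-sequence total mutation rate
  tAbs <- tOut / mu
  nT <- length(tOut)
  hybW <- matrix(NA_integer_, nReps, nT)
  hybWp <- matrix(NA_integer_, nReps, nT)
  statLaw <- if (ancestor == "stationary")
    boltzmannStationary(params, formulaMode) else NULL
  set.seed(seed)
  for (i in seq_len(nReps)) {
    r0 <- if (ancestor == "mode") {
      max(0L, min(rStar, as.integer(round(lc@xi0 / params@epsilon))))
    } else {
      sample.int(ell + 1L, 1L, prob = statLaw) - 1L
    }
    b1 <- sample(c(0L, 1L), ell, replace = TRUE)
    b2 <- b1
    if (r0 > 0L) {
      pos <- sample.int(ell, r0)
      b2[pos] <- 1L - b2[pos]
    }
    linA <- simulateLineageStrings(b1, b2, tAbs, params, rStar, formulaMode)
    linB <- simulateLineageStrings(b1, b2, tAbs, params, rStar, formulaMode)
    for (j in seq_len(nT)) {
      hybW[i, j] <- sum(linA$b1[j, ] != linB$b2[j, ])
      hybWp[i, j] <- sum(linB$b1[j, ] != linA$b2[j, ])
    }
  }
  p <- colMeans(hybW > rStar)
  se <- sqrt(p * (1 - p) / nReps)
  wEnergy <- params@epsilon * hybW
  moments <- data.frame(
    mu_t = tOut,
    meanW = colMeans(wEnergy),
    varW = apply(wEnergy, 2L, var),
    seMeanW = apply(wEnergy, 2L, sd) / sqrt(nReps))
  list(pi = PIResult(times = tOut, pi = p, method = "discrete", mcSE = se,
                     nReps = nReps),
       moments = moments, hybridR = hybW, hybridRPrime = hybWp)
}

#' Single-lineage r-chain kinetic Monte Carlo
#'
#' Simulates the birth-death chain on the mismatch count \eqn{r} alone
#' (no explicit strings), using the rates of [buildRateMatrix()].  Used to
#' validate the explicit-string simulator and the stationary law.
#'
#' @param params a [ModelParams-class] with `mu0` set.
#' @param nEvents number of substitution events to simulate.
#' @param r0 initial mismatch count.
#' @param seed integer seed.
#' @param formulaMode fixation law.
#' @return A list with `r` (state after each event), `dwell` (time spent
#'   in the state preceding each event) and `occupancy` (time-weighted
#'   distribution over \eqn{r = 0, \dots, \ell}).
#' @export
simulateRChain <- function(params, nEvents, r0, seed = 1L,
                           formulaMode = c("diffusion", "wf_exact")) {
  formulaMode <- match.arg(formulaMode)
  if (is.na(params@mu0)) stop("'mu0' must be set for the discrete module")
  ell <- params@ell
  Ne <- params@Ne
  mu0 <- params@mu0
  rStar <- as.integer(floor(params@xiStar / params@epsilon))
  Fr <- fitnessOfR(0:ell, params, rStar)
  kup <- numeric(ell + 1L)
  kdn <- numeric(ell + 1L)
  for (i in 1:(ell + 1L)) {
    rr <- i - 1L
    if (rr < ell) {
      dF <- if (is.infinite(Fr[i + 1L]) && is.infinite(Fr[i])) 0
            else Fr[i + 1L] - Fr[i]
      kup[i] <- 2 * Ne * 2 * mu0 * (ell - rr) *
        fixationProbability(dF, Ne, formulaMode)
    }
    if (rr > 0L) {
      dF <- if (is.infinite(Fr[i - 1L]) && is.infinite(Fr[i])) 0
            else Fr[i - 1L] - Fr[i]
      kdn[i] <- 2 * Ne * 2 * mu0 * rr *
        fixationProbability(dF, Ne, formulaMode)
    }
  }
  set.seed(seed)
  r <- integer(nEvents)
  dwell <- numeric(nEvents)
  cur <- as.integer(r0)
  occ <- numeric(ell + 1L)
  for (e in seq_len(nEvents)) {
    i <- cur + 1L
    tot <- kup[i] + kdn[i]
    dt <- rexp(1L) / tot
    occ[i] <- occ[i] + dt
    cur <- if (runif(1L) < kup[i] / tot) cur + 1L else cur - 1L
    r[e] <- cur
    dwell[e] <- dt
  }
  list(r = r, dwell = dwell, occupancy = occ / sum(occ))
}
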