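## Reproducible experiment drivers: the incompatibility-curve grid over
## population sizes, the density evolution snapshots, and the
## time-to-threshold sweep.  Each driver optionally writes TSV outputs and a
## JSON manifest (full configuration echo + seed + package version) so a run
## can be reproduced exactly.

writeManifest <- function(outDir, name, config) {
  config$package <- as.character(packageVersion("dmiclock"))
  jsonlite::write_json(config,
                       file.path(outDir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

writeTSV <- function(df, outDir, name) {
  write.table(df, file.path(outDir, paste0(name, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

## Fig.-style parameterisation: the curves depend on (mu*t, 4*kappaF*Ne,
## F*/kappaF, ell) only, so the grid over fitness-scaled population size is
## realised at fixed Ne by varying kappaF = g/(4*Ne).
gridParams <- function(fourKappaFNe, ell = 10L, fstarOverKappaF = -25,
                       Ne = 100, mu = 1) {
  modelParams(ell = ell, kappaF = fourKappaFNe / (4 * Ne), Ne = Ne, mu = mu,
              fstarOverKappaF = fstarOverKappaF)
}

#' Incompatibility curves across fitness-scaled population sizes
#'
#' Computes the analytic incompatibility probability \eqn{P_I(\mu t)} on a
#' log-spaced grid for each value of \eqn{4\kappa_F N_e}, plus (optionally)
#' Monte-Carlo estimates from the full-landscape Langevin simulator, and an
#' ordering report: at fixed \eqn{\mu t} the curves decrease with
#' increasing population size in the intermediate regime, and collapse in
#' both extreme-\eqn{N_e} limits.
#'
#' Defaults follow the model's reference configuration: \eqn{\ell = 10},
#' \eqn{F^*/\kappa_F = -25} (so \eqn{\xi^* = \sqrt{50} \approx 7}),
#' ancestor fixed at \eqn{\xi_0}.
#'
#' @param fourKappaFNe numeric grid of fitness-scaled population sizes.
#' @param ell interface length.
#' @param fstarOverKappaF fitness-threshold ratio (negative).
#' @param Ne effective population size used to realise the grid (the
#'   curves depend only on the dimensionless products).
#' @param reps Monte-Carlo replicates per SDE curve.
#' @param sdeGrid subset of `fourKappaFNe` for which to run the simulator
#'   (`NULL` for all; `numeric(0)` for analytic only).
#' @param tauMin,tauMax,nTau analytic time grid (\eqn{\mu t} units).
#' @param sdeTau output times for the simulator (defaults to a coarse
#'   log grid up to `min(tauMax, 10)`).
#' @param seed root seed for the simulator.
#' @param outDir directory for TSV/manifest outputs, or `NULL` to skip
#'   writing.
#' @return A list with `analytic` (long `data.frame`: `fourKappaFNe`,
#'   `mu_t`, `p_i`), `sde` (long `data.frame` with standard errors, or
#'   `NULL`), and `ordering` (`data.frame` of \eqn{P_I} at \eqn{\mu t =
#'   0.1} by grid value).
#' @export
runFigure2 <- function(fourKappaFNe = c(0.001, 0.01, 0.1, 1, 10, 100),
                       ell = 10L, fstarOverKappaF = -25, Ne = 100,
                       reps = 1e4, sdeGrid = NULL,
                       tauMin = 1e-4, tauMax = 10, nTau = 120L,
                       sdeTau = NULL, seed = 1L, outDir = NULL) {
  analytic <- do.call(rbind, lapply(fourKappaFNe, function(g) {
    p <- gridParams(g, ell, fstarOverKappaF, Ne)
    res <- analyticPI(p, tauMin, tauMax, nTau)
    data.frame(fourKappaFNe = g, mu_t = sampleTimes(res),
               p_i = piValues(res))
  }))
  if (is.null(sdeGrid)) sdeGrid <- fourKappaFNe
  sde <- NULL
  if (length(sdeGrid)) {
    if (is.null(sdeTau))
      sdeTau <- exp(seq(log(0.01), log(min(tauMax, 10)), length.out = 12L))
    sde <- do.call(rbind, lapply(sdeGrid, function(g) {
      p <- gridParams(g, ell, fstarOverKappaF, Ne)
      ens <- simulateLineages(p, sdeConfig(reps, tOut = sdeTau, seed = seed,
                                           landscapeMode = "full"))
      est <- empiricalPI(ens)
      data.frame(fourKappaFNe = g, mu_t = sampleTimes(est),
                 pi_hat = piValues(est), se = piStandardError(est))
    }))
  }
  atTau <- 0.1
  ordering <- do.call(rbind, lapply(fourKappaFNe, function(g) {
    p <- gridParams(g, ell, fstarOverKappaF, Ne)
    data.frame(fourKappaFNe = g,
               p_i = dmiProbability(atTau / p@mu, p),
               xi0 = optimalBindingEnergy(p))
  }))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTSV(analytic, outDir, "figure2_analytic")
    if (!is.null(sde)) writeTSV(sde, outDir, "figure2_sde")
    writeTSV(ordering, outDir, "figure2_ordering")
    writeManifest(outDir, "figure2", list(
      fourKappaFNe = fourKappaFNe, ell = ell,
      fstarOverKappaF = fstarOverKappaF, Ne = Ne, reps = reps,
      sdeGrid = sdeGrid, tauMin = tauMin, tauMax = tauMax, nTau = nTau,
      sdeTau = sdeTau, seed = seed))
  }
  list(analytic = analytic, sde = sde, ordering = ordering)
}

## 2-D histogram of two coordinate vectors on a common square grid
hist2d <- function(x, y, bins, lim) {
  br <- seq(lim[1L], lim[2L], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(x, br, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, br, all.inside = TRUE), 1L), bins)
  tab <- matrix(0, bins, bins)
  for (k in seq_along(ix)) tab[ix[k], iy[k]] <- tab[ix[k], iy[k]] + 1
  tab / length(ix)
}

#' Joint density evolution of lineage and hybrid coordinates
#'
#' Simulates the linearised two-lineage dynamics and, at each requested
#' time, bins the joint distributions of \eqn{(x_1, x_2)} (one lineage:
#' co-evolving pair) and \eqn{(x_1, x_2')} (hybrid combination:
#' independent lineages).  Reports
#' \itemize{
#'   \item the product-of-marginals test for the hybrid joint — the mean
#'     absolute deviation between the binned joint and the outer product of
#'     its marginals (the hybrid density factorises;
#'     the within-lineage joint does not once the landscape is felt);
#'   \item the covariance-ellipse axis ratio
#'     \eqn{\sqrt{\lambda_{max}/\lambda_{min}}} of each joint — near 1
#'     while diffusion is neutral (\eqn{2N_e\kappa\mu t \ll 1}), and
#'     \eqn{\gg 1} for the within-lineage joint once the density is
#'     squeezed along the tube \eqn{x_1 = x_2 + \xi_0}.
#' }
#'
#' @param fourKappaFNe fitness-scaled population size.
#' @param times output times (\eqn{\mu t} units).
#' @param reps Monte-Carlo replicates.
#' @param bins histogram bins per axis.
#' @param ell,fstarOverKappaF,Ne model configuration as in [runFigure2()].
#' @param seed root seed.
#' @param outDir directory for TSV/manifest outputs, or `NULL`.
#' @return A `data.frame` with one row per output time: axis ratios of the
#'   two joints and the product-of-marginals deviation (plus its
#'   Monte-Carlo scale `pomNull`, the same metric computed between two
#'   independent halves of the ensemble).
#' @export
runFigure3Density <- function(fourKappaFNe = 1, times = c(0.05, 20),
                              reps = 4000L, bins = 30L, ell = 10L,
                              fstarOverKappaF = -25, Ne = 100, seed = 1L,
                              outDir = NULL) {
  p <- gridParams(fourKappaFNe, ell, fstarOverKappaF, Ne)
  ens <- simulateLineages(p, sdeConfig(reps, tOut = times, seed = seed,
                                       landscapeMode = "linearised"))
  axisRatio <- function(a, b) {
    ev <- eigen(cov(cbind(a, b)), symmetric = TRUE, only.values = TRUE)$values
    sqrt(ev[1L] / ev[2L])
  }
  rows <- lapply(seq_along(times), function(j) {
    x1 <- ens@x1[, j]; x2 <- ens@x2[, j]; x2p <- ens@x2p[, j]
    lim <- range(c(x1, x2, x2p))
    joint <- hist2d(x1, x2p, bins, lim)
    prod <- outer(rowSums(joint), colSums(joint))
    half <- seq_len(floor(reps / 2))
    jA <- hist2d(x1[half], x2p[half], bins, lim)
    jB <- hist2d(x1[-half], x2p[-half], bins, lim)
    data.frame(mu_t = times[j],
               axisRatioLineage = axisRatio(x1, x2),
               axisRatioHybrid = axisRatio(x1, x2p),
               pomDeviation = mean(abs(joint - prod)),
               pomNull = mean(abs(jA - jB)))
  })
  res <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTSV(res, outDir, "figure3_density_metrics")
    writeManifest(outDir, "figure3", list(
      fourKappaFNe = fourKappaFNe, times = times, reps = reps, bins = bins,
      ell = ell, fstarOverKappaF = fstarOverKappaF, Ne = Ne, seed = seed))
  }
  res
}

#' Time to the speciation threshold versus population size
#'
#' For each effective population size, solves (on the analytic curve, by
#' bisection in \eqn{\log t}) for the divergence time at which
#' \eqn{P_I(t)} reaches the threshold (default \eqn{10^{-5}}, one expected
#' DMI among \eqn{M \sim 10^5} interacting pairs), and reports the
#' phenotypic distance to the boundary \eqn{\xi^* - \xi_0}.  Both are
#' increasing in \eqn{N_e}: larger populations sit further from the
#' boundary and take longer to speciate.
#'
#' @param NeGrid numeric vector of effective population sizes.
#' @param kappaF fitness curvature (fixed across the sweep).
#' @param ell,fstarOverKappaF model configuration.
#' @param mu diffusion rate.
#' @param threshold target probability.
#' @param outDir directory for TSV/manifest outputs, or `NULL`.
#' @return A `data.frame` with columns `Ne`, `fourKappaFNe`,
#'   `tThreshold` (in \eqn{\mu t} units; `NA` if unreachable, flagged in
#'   `reachable`), and `xiStarMinusXi0`.
#' @export
runPopsizeSweep <- function(NeGrid = c(1, 10, 100, 1000), kappaF = 0.0025,
                            ell = 10L, fstarOverKappaF = -25, mu = 1,
                            threshold = speciationThreshold(1e5),
                            outDir = NULL) {
  rows <- lapply(NeGrid, function(ne) {
    p <- modelParams(ell = ell, kappaF = kappaF, Ne = ne, mu = mu,
                     fstarOverKappaF = fstarOverKappaF)
    tt <- suppressWarnings(dmiThresholdTime(p, threshold))
    data.frame(Ne = ne, fourKappaFNe = 4 * kappaF * ne,
               tThreshold = tt, reachable = !is.na(tt),
               xiStarMinusXi0 = xiStar(p) - optimalBindingEnergy(p))
  })
  res <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTSV(res, outDir, "popsize_sweep")
    writeManifest(outDir, "popsize_sweep", list(
      NeGrid = NeGrid, kappaF = kappaF, ell = ell,
      fstarOverKappaF = fstarOverKappaF, mu = mu, threshold = threshold))
  }
  res
}
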