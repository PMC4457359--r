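---
title: "Methods: coarse-grained TF-DNA coevolution and the growth of hybrid incompatibilities"
author: "dmiclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained TF-DNA coevolution and the growth of hybrid incompatibilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmiclock)
```

## The model and its assumptions

`dmiclock` studies a pair of interacting loci — a transcription factor's
DNA-binding interface and its binding site — reduced to two binary strings
of length $\ell$. The phenotype under selection is the binding energy
$\xi = \epsilon r$, where $r$ is the mismatch (Hamming-type) count between
the strings. This two-state reduction assumes approximately additive
per-position contributions to binding, with one energy scale $\epsilon$
per non-optimal contact; $\epsilon = 1$ by default so $\xi$ is counted in
mismatch units, but it is kept as a parameter so that results can be
reported in physical energy units.

Three modelling assumptions drive everything else:

1. **Weak mutation (monomorphic) regime.** With per-site mutation rate
   $\mu_0$ and $n = 2\ell$ mutable sites, $n\mu_0 N_e \ll 1$: the
   population is a single genotype that sequentially fixes or loses
   mutations. The constructor warns when a supplied $\mu_0$ puts the
   diagnostic $2\ell\mu_0 N_e$ at or above 0.1.
2. **Truncated quadratic log fitness.** $F(\xi) = -\tfrac12\kappa_F\xi^2$
   up to an inviability boundary $\xi^*$, $-\infty$ beyond, where
   non-specific genomic binding outcompetes the target site. $\xi^*$ can
   be given directly or through the threshold ratio $F^*/\kappa_F$ via
   $\xi^* = \sqrt{-2F^*/\kappa_F}$.
3. **Sequence entropy.** Many string pairs share one $r$;
   $S(r) = \ln\binom{\ell}{r}$, approximated in the continuum by the
   quadratic $-(2/\ell)(\xi - \ell/2)^2$. Its additive constant is
   dropped: only gradients enter the dynamics, and densities are
   normalised numerically.

Origin-fixation dynamics with a fixation law satisfying the
detailed-balance (Sella–Hirsh) condition make
$p(\xi) \propto e^{4N_e\Phi(\xi)}$ stationary, with free fitness
$\Phi = F + S/(4N_e)$. In the continuum this yields Smoluchowski/Langevin
dynamics with diffusion rate $\mu$ per component and drift
$2N_e\mu\,\partial\Phi/\partial\xi$ — the response coefficient is fixed by
requiring zero probability flux at equilibrium (`probabilityFlux()` checks
this identity numerically). Because both $F$ and the continuous $S$ are
quadratic, $\Phi$ completes the square *exactly* on the viable domain:
curvature $\kappa = \kappa_F + 1/(\ell N_e)$, maximum
$\xi_0 = 1/(2\kappa N_e)$, width $\Delta\xi = 1/\sqrt{4\kappa N_e}$
(`landscapeConstants()`), and the package asserts the identity at
$10^{-10}$ relative tolerance in its tests.

Two lineages split from a common ancestor and evolve independently; free
recombination in hybrids pairs $x_1$ with $x_2'$ (and $x_1'$ with $x_2$).
The linearised dynamics give Gaussian hybrid energies with constant mean
$\xi_0$ and variance
$\Sigma_{11}(t) = \mu t + (8N_e\kappa)^{-1}(1 - e^{-8N_e\kappa\mu t})$,
whence the incompatibility probability `dmiProbability()` as a sum of two
complementary error functions. The mechanism for the population-size
dependence is entirely contained in $\xi_0(N_e)$: entropy poises small
populations nearer the boundary.

## Parameters that matter

| parameter | meaning | units | default / rationale |
|---|---|---|---|
| `ell` | interface length | sites | 10 in the reference configuration; enters both the entropy curvature $1/(\ell N_e)$ and the entropy optimum $\ell/2$ |
| `kappaF` | fitness curvature | (binding energy)$^{-2}$ | set via the dimensionless $4\kappa_F N_e$; the model depends only on $(\mu t, 4\kappa_F N_e, F^*/\kappa_F, \ell)$ |
| `Ne` | effective population size | individuals (diploid) | $\ge 1$ enforced; grids over $4\kappa_F N_e$ are realised at fixed `Ne = 100` by varying `kappaF` |
| `mu` | phenotypic diffusion rate per component | (time)$^{-1}$ | 1, so times are read as $\mu t$ |
| `xiStar` / `fstarOverKappaF` | inviability boundary | binding energy | reference $F^*/\kappa_F = -25$, i.e. $\xi^* = \sqrt{50} \approx 7$ |
| `epsilon` | energy per mismatch | energy | 1 |
| `mu0` | per-site mutation rate (discrete module only) | (time)$^{-1}$ | chosen to keep $2\ell\mu_0 N_e < 0.1$ |

The mapping between the continuous and discrete clocks is
$\mu = \ell\mu_0$: the per-sequence total mutation rate. This choice makes
the short-time hybrid variance open at exactly $2\mu t$ in both pictures
(each of the two interacting sequences contributes an independent
diffusion at rate $\mu$), and it is the convention used whenever Gillespie
time is converted to $\mu t$.

## The simulators: what they emulate, and what they do not

**Langevin ensemble (`simulateLineages()`).** Time is integrated in the
dimensionless variable $\tau = \mu t$, in which the only drift coefficient
is $a = 2N_e\kappa$ and the per-component noise variance per unit time
is 1. Euler–Maruyama is used with default step
$\mathrm{d}t = \min(0.01,\ 0.1/(4N_e\kappa))$, which resolves the
relaxation rate uniformly across population sizes; a larger user-supplied
step triggers a warning. Each interval between requested output times is
split into $\lceil\Delta/\mathrm{d}t\rceil$ equal substeps, so the
effective step never exceeds the nominal one and output times are hit
exactly. Two landscape modes are provided: `"full"` keeps the cusped
double-well drift in $x_1 - x_2$ (with the tie-break `sign(0) = 0` at the
cusp, no smoothing — the drift is bounded, which Euler–Maruyama tolerates),
and `"linearised"` uses the single-peak quadratic that underlies the closed
forms. The inviability boundary is *not* enforced on lineages by default:
at the short times relevant to speciation, lineages essentially never reach
$\xi^*$; a reflecting option (`boundaryMode = "reflect"`) exists for
sensitivity analysis. An incompatibility is the instantaneous event
$|w(t)| > \xi^*$, matching the Gaussian-integral definition of the theory —
it is not a first-passage time.

**Discrete origin-fixation simulator (`gillespieTwoLineages()`).**
Explicit binary string pairs ($\ell$ up to a few hundred) evolve by
kinetic Monte Carlo: a flip of either sequence at any of the $\ell - r$
matched positions raises $r$, at any of the $r$ mismatched positions
lowers it, each candidate weighted by a diploid fixation probability.
The supply of candidate mutations is $2N_e$ gene copies times the
per-copy rate, so with the neutral fixation probability $1/(2N_e)$ the
neutral substitution rate equals the mutation rate — the normalisation
that makes the chain's variance grow as $2\mu t$ and lets Gillespie time
convert to $\mu t$. Two fixation laws are available:
`"diffusion"` ($\pi(s) = 2s/(1 - e^{-4N_e s})$, detailed-balance constant
$\nu = 4N_e$, the default, matching the stationary law as written) and
`"wf_exact"` ($\pi(s) = (1-e^{-2s})/(1-e^{-4N_e s})$,
$\nu = 2(2N_e - 1)$). Fixation into inviable classes ($r > r^*$ with
$r^* = \lfloor\xi^*/\epsilon\rfloor$) has probability zero. Explicit
strings are kept — rather than the $r$-chain alone — because hybrid
mismatch counts depend on *which* positions differ, not only how many.
The $r$-chain (`buildRateMatrix()`, `simulateRChain()`) is used for
stationary-law and master-equation analysis, where the load-bearing
theorem is detailed balance against the truncated Boltzmann–binomial law
$p(r) \propto \binom{\ell}{r}e^{\nu F(r)}$, asserted rate-by-rate at
$10^{-10}$ and as a total-variation distance below $10^{-8}$ between the
closed form and an independent null-space solve of the generator.

Neither simulator emulates polymorphism, clonal interference,
recombination within lineages (irrelevant in the monomorphic regime),
more than two loci or lineages, quaternary alphabets, or
position-specific energy matrices. Passing tests therefore demonstrate
the internal consistency of the coarse-graining chain
(strings → $r$-chain → diffusion → closed form), not the fidelity of the
two-state binary reduction to real TF-TFBS energetics.

## Numerical choices

* $-\infty$ log fitness is an ordinary IEEE value: it propagates through
  `exp()` as probability zero and never raises an exception.
* The complementary error function is evaluated through the Gaussian tail
  `pnorm(..., lower.tail = FALSE)`, accurate to the bottom decades
  ($P_I \sim 10^{-12}$ and far below); `expm1` guards the saturating
  exponentials at short times, so the $t \to 0$ coefficient
  $\Sigma_{11}/\mu t \to 2$ is exact to rounding.
* At $t = 0$ the hybrid Gaussian is degenerate; `dmiProbability()` returns
  the closed-form limit (the indicator $|\xi_0| > \xi^*$, i.e. 0 for any
  viable ancestor) instead of evaluating 0/0.
* The fixation laws switch to series expansions about the neutral limit
  for $|4N_e\Delta F| < 10^{-6}$; the transition between inviable classes
  (never visited at stationarity) uses the conventions $\pi(+\infty) = 1$
  and $\Delta F = 0$ between two $-\infty$ states.
* Closed-form identities are asserted at $10^{-10}$ relative tolerance;
  quadrature identities at $10^{-6}$; Monte-Carlo checks at three standard
  errors.
* Reproducibility: the Langevin ensemble partitions replicates into fixed
  blocks of 1000 whose stream seeds are drawn from a master stream, and
  the Gillespie replicates consume consecutive segments of one stream —
  both make enlarging the replicate count append new replicates without
  changing earlier ones. Sequential raw seeds (`seed + i`) were rejected:
  R's Mersenne–Twister produces measurably correlated short streams under
  consecutive seeds, which biased Gillespie trajectories of a few dozen
  draws each.
* The common ancestor defaults to the free-fitness maximum
  ($\xi(0) = \xi_0$; discrete: the stationary mode $\mathrm{round}(\xi_0)$)
  to match the closed forms; sampling the ancestor from the equilibrium
  law is available in both simulators, since a dispersed ancestor is the
  more realistic initial condition and broadens the early-time hybrid
  distribution at small population sizes.
* P_I estimation defaults to one hybrid per replicate (`w_only`): the two
  hybrids of a replicate are anti-correlated at long times, so pooling
  them changes the standard error but not the mean; `pooled` is provided
  and agrees within combined errors.

## Design decisions in open territory

* **Curve comparisons across population sizes.** Near the probability
  floor the log-log curves are nearly vertical, so vertical (probability-
  ratio) metrics are dominated by tiny horizontal offsets. The saturation
  ("curve collapse") diagnostics therefore compare threshold-crossing
  times: a decade of $N_e$ in either saturated limit moves the crossing
  times by under 0.05 dex at every probability level from $10^{-12}$ to
  $0.1$, against ~0.7 dex per decade mid-regime.
* **Discrete/continuum boundary alignment.** The discrete incompatibility
  event is $r > r^*$ on integers while the continuum computes
  $P(|w| > \xi^*)$; placing $\xi^*$ at a half-integer (so
  $r^* = \lfloor\xi^*\rfloor$ and the two events coincide) removes a
  half-unit continuity-correction bias when validating the discrete
  simulator against the closed form.
* **Equilibrium-density domains.** Both the truncated magnitude domain
  $[0, \xi^*]$ and the unbounded linearised Gaussian are exposed; the
  unbounded form is the default because the closed-form hybrid theory is
  built on it.

## Problem sizes used by the test-suite checks

The package's stochastic checks run at desk scale: $10^4$ replicates for
the moment-matching, fitness-slope and incompatibility-curve comparisons
(output grids up to $\mu t = 10$), $2\,000$–$4\,000$ replicates for
equilibrium-recovery and density-evolution diagnostics, $2\,000$
Gillespie replicate pairs at $\ell = 200$ for the continuum-agreement
check, and $10^5$ events for the master-equation occupancy check. The
figure-style drivers default to $10^4$ replicates and accept larger
values through their `reps` argument.

## Known limitations

* **Well flipping at intermediate population sizes.** The closed form
  linearises around the $+\xi_0$ well, but the full landscape is a double
  well in $x_1 - x_2$ with a cusp barrier of only
  $2N_e\kappa\xi_0^2 \approx 1.4$ (in $4N_e\Phi$ units) at
  $4\kappa_F N_e = 1$. Lineages then flip wells on the relaxation
  timescale, pulling the hybrid mean toward zero: the full-landscape
  simulation runs ~15% below the analytic $P_I$ by $\mu t \gtrsim 5$ at
  that parameter point (a systematic several-standard-error deviation at
  $10^4$ replicates), while the two agree within Monte-Carlo error across
  the rest of the population-size grid and everywhere at short times. The
  closed form is an approximation for the short-time, single-well regime
  it was derived in.
* **Finite sequence length.** The continuum hybrid diffuses without
  bound, but the discrete hybrid mismatch saturates toward the binomial
  optimum $\ell/2$ (variance bounded by $\ell/4$, mean reverting at rate
  $\sim 4\mu/\ell$). Discrete-continuum agreement therefore requires
  $\mu t \ll \ell/8$ and near-neutral per-step fitness differences
  ($4N_e\kappa_F\xi_0$ small); the continuum clock overestimates $P_I$
  outside that window.
* **Truncation bias.** Strictly $\langle\xi\rangle \ne \xi_0$ once the
  landscape is truncated at $\xi = 0$ and $\xi^*$; the bias is small for
  $\Delta\xi \ll \min(\xi_0, \xi^* - \xi_0)$ and is visible only through
  the simulators, not the closed forms.
* At very large $4\kappa_F N_e$, real sequence evolution feels the
  discreteness of fitness steps and the substitution rate slows; the
  coarse-grained theory deliberately does not model this regime.
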