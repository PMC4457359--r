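# dmiclock

Why do smaller populations appear to speciate faster? `dmiclock` implements a
coarse-grained biophysical model of the coevolution between a transcription
factor (TF) and its DNA binding site (TFBS), and of how that coevolution in
two geographically isolated lineages produces Dobzhansky–Muller
incompatibilities (DMIs) in their hybrids. It is aimed at population
geneticists and evolutionary modellers who want a tractable, quantitative
speciation clock in the weak-mutation (monomorphic) regime, together with the
simulators needed to check every step of the coarse-graining.

## The model

The TF interface and its binding site are reduced to binary strings of
length ℓ; the binding energy phenotype is ξ = εr, with r the number of
mismatches between them (ε = 1 by default). Log fitness is a truncated
quadratic,

    F(ξ) = -½ κ_F ξ²   for |ξ| ≤ ξ*,   -∞ beyond,

where ξ* is the inviability boundary (non-specific binding wins past it).
Because many sequence pairs share one mismatch count, evolution also feels
the **sequence entropy** S(ξ) = ln C(ℓ, r) ≈ -(2/ℓ)(ξ - ℓ/2)². In the
weak-mutation regime (n μ₀ N_e ≪ 1), origin-fixation dynamics are driven by
the **free fitness**

    Φ(ξ) = F(ξ) + S(ξ)/(4 N_e),

which is again quadratic with curvature κ = κ_F + 1/(ℓ N_e), maximum
ξ₀ = 1/(2 κ N_e) and equilibrium width Δξ = (4 κ N_e)^{-1/2}. The phenotype
diffuses (Smoluchowski/Langevin dynamics) with diffusion rate μ and drift
2 N_e μ ∂Φ/∂ξ — the evolutionary analogue of the Einstein relation, fixed by
requiring zero flux at the Boltzmann equilibrium p(ξ) ∝ exp(4 N_e Φ).

Two lineages split from a common ancestor at ξ₀ and evolve independently.
Free recombination in hybrids combines alleles across lineages, giving hybrid
binding energies w = x₁ - x₂′ and w′ = x₁′ - x₂ with

    ⟨w⟩   = ξ₀,
    Σ₁₁(t) = μt + (8 N_e κ)^{-1} (1 - e^{-8 N_e κ μ t}),

and the probability that a hybrid is incompatible (|w| > ξ*) is

    P_I(t) = ½ erfc[(ξ* - ⟨w⟩)/√(2Σ₁₁)] + ½ erfc[(ξ* + ⟨w⟩)/√(2Σ₁₁)].

Sequence entropy poises smaller populations closer to ξ* (ξ₀ grows toward
ℓ/2 as N_e shrinks), so their hybrids have less distance to diffuse: the
model predicts faster speciation at small N_e, saturating in both extreme
population-size limits.

Three routes to P_I(t) are implemented and cross-validated:

* **analytic** — the closed forms above (`dmiProbability()`,
  `hybridCovariance()`, `hybridFitnessMean()`);
* **sde** — Euler–Maruyama Monte Carlo of the coupled Langevin equations,
  on the full cusped landscape or its linearisation (`simulateLineages()`,
  `empiricalPI()`);
* **discrete** — kinetic Monte Carlo on explicit binary string pairs with a
  diploid origin-fixation law, plus the tridiagonal master-equation chain on
  r whose stationary law is the truncated Boltzmann–binomial distribution
  (`gillespieTwoLineages()`, `buildRateMatrix()`).

## Worked example

```r
library(dmiclock)

p <- modelParams(ell = 10, kappaF = 0.0025, Ne = 100, fstarOverKappaF = -25)
p
#> ModelParams
#>   ell = 10, kappaF = 0.0025, Ne = 100, mu = 1
#>   xiStar = 7.07107, epsilon = 1, mu0 = NA
#>   derived: kappa = 0.0035, xi0 = 1.42857, deltaXi = 0.845154, 4*Ne*kappaF = 1
```

The fitness-threshold ratio F*/κ_F = -25 places the inviability boundary at
ξ* = √50 ≈ 7 mismatch units; at 4 κ_F N_e = 1 the balance of selection and
sequence entropy puts the ancestor at ξ₀ ≈ 1.43, well inside the boundary.

```r
dmiProbability(c(1, 5, 10), p)
#> [1] 0.000001 0.007508 0.043909
```

An incompatibility needs time to diffuse into reach: essentially zero
probability at μt = 1, about 0.75% of hybrids by μt = 5, 4.4% by μt = 10.
The Monte-Carlo simulator on the full (cusped) landscape reproduces the
curve within sampling error:

```r
ens <- simulateLineages(p, sdeConfig(2000, tOut = c(1, 5, 10), seed = 1))
as.data.frame(empiricalPI(ens))
#>   mu_t    p_i          se method
#> 1    1 0.0000 0.000000000    sde
#> 2    5 0.0055 0.001653746    sde
#> 3   10 0.0400 0.004381780    sde
```

The population-size effect, as time for P_I to reach the speciation
threshold 1/M with M = 10⁵ interacting locus pairs:

```r
runPopsizeSweep(NeGrid = c(10, 100, 1000), kappaF = 0.0025)
#>     Ne fourKappaFNe tThreshold reachable xiStarMinusXi0
#> 1   10          0.1     0.2768      TRUE          3.071
#> 2  100          1.0     1.4003      TRUE          5.642
#> 3 1000         10.0     2.4789      TRUE          6.879
```

A hundred-fold larger population takes about nine times longer (in μt units)
to reach the threshold, because its ancestor sits 6.9 rather than 3.1
binding-energy units from the boundary.

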