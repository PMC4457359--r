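Package: dmiclock
Title: Coarse-Grained Stochastic Dynamics of TF-DNA Coevolution and Hybrid
    Incompatibility Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the coevolution of a transcription factor and its DNA
    binding site in geographically isolated lineages and the resulting growth
    of Dobzhansky-Muller incompatibilities in hybrids. Implements the free
    fitness landscape (log fitness plus sequence entropy over effective
    population size), the closed-form solution of the linearised two-lineage
    Langevin dynamics with its complementary-error-function incompatibility
    probability, an Euler-Maruyama Monte-Carlo simulator of the coupled
    stochastic differential equations, and a discrete binary-string
    origin-fixation simulator with its tridiagonal master-equation chain on
    mismatch count. Includes reproducible experiment drivers exposing the
    population-size dependence of the speciation clock.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix
Config/testthat/edition: 3
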