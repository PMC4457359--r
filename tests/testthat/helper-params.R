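# Reference configuration: ell = 10, F*/kappaF = -25 (xi* = sqrt(50) ~ 7),
# with the fitness-scaled population size 4*kappaF*Ne realised at fixed
# Ne = 100 by varying kappaF.
refParams <- function(fourKappaFNe = 1, ell = 10L, Ne = 100, mu = 1,
                      fstar = -25, mu0 = NA_real_) {
  modelParams(ell = ell, kappaF = fourKappaFNe / (4 * Ne), Ne = Ne, mu = mu,
              fstarOverKappaF = fstar, mu0 = mu0)
}

# Weighted mean/variance of a gridded density (trapezoid weights absorbed
# by the uniform grid).
gridMoments <- function(d) {
  w <- d$p / sum(d$p)
  m <- sum(w * d$xi)
  list(mean = m, var = sum(w * (d$xi - m)^2))
}
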