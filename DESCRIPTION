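Package: ftcopula
Title: Factor Tree Copula Models for Ordinal Item Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combined factor/truncated-vine copula models for ordinal
    item-response data. Items are linked to one or two standard-uniform
    latent factors by parametric bivariate copulas (normal, Student-t,
    Gumbel, survival Gumbel, Frank) and the residual dependence given the
    factors follows a Markov tree (1-truncated vine) of conditional
    bivariate copulas. Provides Gauss-Legendre evaluation of the joint
    probability mass function, two-step IFM estimation with standard
    errors and AIC, polychoric and semi-correlation diagnostics,
    spanning-tree structure selection, sequential copula-family
    selection, Vuong model comparison, exact model-based simulation and
    a simulation-study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
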