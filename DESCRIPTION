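Package: patchsde
Title: Stochastic Population Dynamics in Patchy Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for density-dependent stochastic population models on n
    habitat patches coupled by dispersal and driven by (possibly degenerate,
    spatially correlated) environmental noise. Provides model constructors with
    admissibility checks (dispersal irreducibility, competition growth bounds,
    noise rank), seeded Euler-Maruyama integrators for the abundance system,
    its proportion/total decomposition and the competition-free simplex
    process, and several routes to the stochastic growth rate r whose sign
    separates persistence from extinction: Monte Carlo time averaging,
    quadrature against explicit two-patch stationary densities built by the
    scale/speed construction, and closed forms for perfectly correlated noise.
    Diagnostics turn the theory into executable checks: persistence
    classification, occupation measures near the extinction boundary,
    extinction-rate recovery from log-abundance slopes, synchronization on the
    degenerate manifold, the infinite-dispersal limit, and robustness under
    bounded model perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
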