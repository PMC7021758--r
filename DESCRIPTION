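Package: ecogames
Title: Eco-Evolutionary Game Dynamics with Environmental Feedback
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-strategy evolutionary games
    bidirectionally coupled to a dynamic environment. Payoffs are linear in
    both the strategy frequency and a normalized environmental state, and the
    environment is governed by a self-renewing resource, a decaying resource
    (pollutant), or a distribution of tipping points. The package enumerates
    fixed points analytically, classifies their stability, locates the
    critical environmental-feedback speed at which an interior equilibrium
    loses stability in a Hopf bifurcation, classifies global dynamical
    regimes, detects limit cycles and basins of attraction by adaptive
    numerical integration, and ships case-study parameterizations for
    common-pool resource harvesting, grass-legume competition, and
    tipping-point environments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    numDeriv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
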