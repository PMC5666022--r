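Package: antdrip
Title: Agent-Based Simulation of Ant Droplet Dynamics on a Lattice
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the growth and dripping of hanging aggregations of
    ants on a two-dimensional lattice.  Agents enter at a rod, descend and
    settle into a chain-like structure, share the weight of the agents they
    support, propagate warning signals when overloaded, and adaptively
    coordinate their weight thresholds from local pattern stability; when a
    threshold is breached the supported set detaches as a droplet.  Includes
    the derived observables (interdrop intervals, increments, droplet sizes,
    structure aspect ratios) and the time-series statistics used to
    characterise the droplet dynamics: the fluctuation-function scaling
    exponent, maximum-likelihood power-law (Levy) and shifted-exponential
    fits compared by Akaike weights, and a log-binned G-test of fit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
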