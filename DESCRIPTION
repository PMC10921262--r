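Package: prebotc
Title: Conductance-Based preBotzinger Complex Networks Under Opioid Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates random 300-neuron conductance-based models of the
    preBotzinger complex, the inspiratory rhythm generator, with
    persistent-sodium (Butera-type) bursting dynamics and mu-opioid-receptor
    mediated hyperpolarization and synaptic depression. Provides generators
    for random directed networks with heterogeneous leak and persistent-sodium
    conductances, a fast fixed-step exponential-Euler integrator, protocols
    for gradual opioid ramps and timed all-or-nothing perturbations,
    population-burst detection with shutdown-dose estimation, classification
    of intrinsic activity (silent, bursting, tonic) under synaptic block,
    conductance phase diagrams, and connectivity-versus-sensitivity
    correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
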