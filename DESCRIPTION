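Package: corticogen
Title: Population Dynamics of Cortical Neurogenesis and Founder-Pool Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic two-population model of mammalian cortical
    neurogenesis. Progenitors divide symmetrically (self-amplifying),
    asymmetrically (one progenitor, one neuron) or symmetrically
    neurogenically (two neurons), with piecewise-linear time-dependent
    division-mode probabilities and a constant or age-dependent cell-cycle
    length. The package simulates progenitor and neuron trajectories with a
    fixed-step Runge-Kutta integrator, recovers species-specific division
    strategies by exhaustive grid search against a deeper-layer neuron
    fraction constraint, quantifies local parameter sensitivity, and
    estimates the founder progenitor population by rejection approximate
    Bayesian computation, with packaged parameter sets for mouse, macaque
    and human.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
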