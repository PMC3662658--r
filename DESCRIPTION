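Package: tcswitch
Title: Detecting Excitability Switches in Conductance-Based Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the switch between restorative and
    regenerative excitability in arbitrary conductance-based neuron models.
    Slow gating variables are classified by the sign of their voltage-feedback
    weight, and the balance equation over slow channels is solved together
    with the fast-subsystem singularity condition to locate the transcritical
    bifurcation that organizes the switch. Includes fixed-point continuation
    with saddle-node, Hopf and transcritical event detection, an affine
    applied-current reparametrization that keeps the steady net current
    constant along the bifurcation parameter, stiff ODE simulation of
    electrophysiological signatures (spike latency, afterdepolarization,
    plateau oscillations, bistability), built-in Hodgkin-Huxley and planar
    fixture models, a seeded synthetic-model generator, and JSON/YAML model
    specification input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
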