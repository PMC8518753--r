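Package: phipflow
Title: Kinetic and Microfluidic Transport Modelling of Parahydrogen-Induced
    Polarisation Hydrogenation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic modelling, rate-constant calibration, and
    spatially resolved transport simulation for continuous-flow parahydrogen
    induced polarisation (PHIP) chemistry. Implements the six-reaction,
    ten-species network for propargyl acetate hydrogenation over a rhodium
    catalyst, weighted nonlinear least-squares estimation of the rate
    constants from tube NMR concentration time series with Wald confidence
    intervals, a synthetic tube-experiment data generator, and a steady-state
    two-dimensional finite-volume convection-diffusion-reaction model of a
    membrane-fed microfluidic chip that predicts hydrogen uptake and
    hyperpolarised-product yield in the detection chamber as a function of
    flow rate, including flow-rate optimisation and device-improvement
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
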