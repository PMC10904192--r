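Package: odisco
Title: Online Discovery of Governing Equations via Adaptive Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the governing ordinary differential equations of a
    dynamical system from noisy, uniformly sampled time-series measurements.
    A wide library of candidate basis functions (constants, monomials,
    trigonometric, rational and custom terms) is combined with a recursive
    adaptive observer that jointly estimates the state and the library
    coefficients with exponential forgetting, so discovery runs online
    without batch optimisation. Includes simulators for standard benchmark
    systems (mass-spring-damper, Lorenz, Roessler, Lotka-Volterra,
    Van der Pol, a linear control system and a magnetic levitation model),
    a persistent-excitation diagnostic based on windowed regressor
    Gramians, accuracy/convergence scoring against known truth, and
    delimited-text input/output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
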