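Package: diabsde
Title: Stochastic Diabetes Compartment Model with Additive Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-compartment Ito stochastic differential
    equation for the prevalence of diabetes with and without
    complications, driven by a single Brownian motion with additive
    sinusoidal noise and time-proportional transition rates.  Provides
    Euler-Maruyama and Milstein one-step integrators, seeded Wiener path
    generation with dyadic coarsening and negative-time reflection,
    through-origin least-squares calibration of the rate coefficients
    from yearly surveillance tables, a closed-form matrix-exponential
    oracle for the noise-free system, and diagnostics that estimate the
    strong (mean-square) convergence order and verify pullback
    mean-square asymptotic stability empirically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
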