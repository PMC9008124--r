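Package: csppk
Title: Computational Singular Perturbation Diagnostics for Multiscale
    Kinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Timescale decomposition and model-reduction diagnostics for
    stiff mass-action kinetic networks, built around the Computational
    Singular Perturbation (CSP) method. Provides the fast/slow basis
    decomposition of the Jacobian, mode amplitudes and timescales,
    exhausted-mode counting, and the four CSP indices (amplitude
    participation, timescale participation, pointer, importance index),
    together with quasi-steady-state reduced models, their higher-order
    corrections, constraint-error metrics, and rate-constant perturbation
    experiments. Ships the two-compartment FcRn-mediated IgG recycling
    pharmacokinetic model as the worked system, plus a randomized
    parameter-set generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
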