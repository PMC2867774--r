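Package: swcme
Title: Sliding-Window Numerical Solution of the Chemical Master Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transient analysis of stochastic chemical kinetics by direct
    numerical solution of the chemical master equation. Instead of solving
    over the full (possibly infinite) reachable state space, the solver
    tracks a finite "window" of states that follows the moving probability
    mass: each step predicts per-species population bounds from worst-case
    deterministic branch iterations, restricts the generator matrix to the
    window, and propagates the distribution with either uniformization
    (Poisson-weighted powers of the uniformized transition matrix) or an
    adaptive Krylov-subspace matrix exponential. All probability mass lost
    to thresholding and window leakage is audited, so the result carries a
    rigorous total-error ledger. Ships reaction-network modelling tools
    (mass-action and custom propensities, conservation-law detection,
    reachability analysis), a structured text model format, example
    networks from the stochastic-kinetics literature, and independent
    reference solvers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
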