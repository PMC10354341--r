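Package: neuroloop
Title: Closed-Loop Neurostimulation Controller Design and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for fully adaptive closed-loop neurostimulation
    that reshapes the power spectral density of observed brain activity.
    Implements linear time-invariant system algebra (transfer functions,
    state-space realizations, zero-order-hold discretization, closed-loop
    assembly with feedback delay), Welch spectral estimation with band
    activity metrics, magnitude-only vector fitting of a stable brain
    input-response model from stimulated versus resting spectra, controller
    synthesis from a user-defined band-shaping filter, feedback-delay
    compensation with a chained one-pole negative-group-delay predictor,
    PI and LQG reference-tracking baselines with Smith predictors, and two
    simulated plants: a noise-driven linear two-population neural mass model
    and a delayed nonlinear cortico-thalamic model with healthy and
    pathological alpha/gamma regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
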