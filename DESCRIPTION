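Package: steercost
Title: Cost-Function Inference for Time-Constrained Steering Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a time-constrained joystick steering task in which a ball
    driven by first-order dynamics and Wiener position noise must reach one of
    one or two targets at a fixed final time, computes optimal feedback control
    policies under a standard cost (quadratic control effort plus quadratic end
    cost) and an extended cost that adds a bounded, time-integrated position
    error, and decides between the two cost models by cross-validated trajectory
    fitting with an exact paired sign test. Includes closed-form linear-quadratic
    and path-integral (linearly-solvable) controllers, log-domain backward
    grid recursions for the extended model, a synthetic-subject generator with
    reaction time, sensorimotor delay and motor noise, and the full
    cross-validation and delay-sensitivity analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
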