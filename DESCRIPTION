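Package: doublestep
Title: Simulation and Kinematic Decoding of Double-Step Reaching Movements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how reaching goals and intermediate hand
    positions can be predicted from past kinematics in the double-step
    reaching paradigm, where a target can jump mid-movement in direction
    (horizontal) or depth (sagittal). Provides a seeded simulator of
    double-step reaching sessions (minimum-jerk movements with superposed
    corrective submovements, fingertip and wrist markers sampled at 100 Hz),
    kinematic analyses (lateral-velocity deviation-time detection, endpoint
    accuracy, reaction times, trajectory variability at peak velocity),
    sliding-window decoding of reaching goals and of future trajectory values
    with a gated recurrent unit network trained by backpropagation through
    time, and time-resolved statistics on accuracy curves (permutation
    Hotelling-type curve comparisons, chance-crossing times, confidence
    ellipses, distributional tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
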