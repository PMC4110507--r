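Package: tremorkin
Title: Sensor-Location Identification and Tremor Estimation from Wearable
    Orientation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing upper-limb movement-disorder kinematics
    recorded by body-worn orientation sensors (MIMUs). Implements
    training-free identification of the relative location of sensors on the
    hand-forearm-humerus chain by ranking magnitude-monotone angular-velocity
    features (with random-forest and pruned decision-tree alternatives), and
    real-time separation of tremulous from voluntary movement with a
    critically damped g-h tracking filter whose smoothing parameter is tuned
    by a genetic algorithm against a zero-phase low-pass offline reference.
    Includes the kinematic tracking error (KTE) metric, spectral summaries, a
    synthetic finger-to-nose trial generator with ground-truth decomposition,
    plain-text trial I/O, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
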