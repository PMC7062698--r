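Package: eegconflict
Title: Single-Trial EEG Decoding of Hand and Conflict States in the Simon Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, decoding and interpretation pipeline for
    single-trial electroencephalography (EEG) recorded during a Simon conflict
    task. Generates synthetic 60-channel Simon-task cohorts with planted
    event-related components and 1/f background noise; applies the standard
    preprocessing chain (zero-phase band-pass, stimulus-locked segmentation,
    amplitude-based artifact rejection, spherical-spline current source density,
    baseline correction); classifies trials into the four hand-by-conflict
    classes with a compact two-block convolutional network (temporal, depthwise
    spatial and separable convolutions) trained with ADAM under
    leave-one-subject-out cross-validation; establishes per-subject significance
    with a binomial chance-level threshold; interprets trained models with
    class-averaged input-gradient saliency maps; and analyses the accompanying
    behavioral tables with closed-form 2x2 repeated-measures ANOVAs. A
    radial-kernel support vector machine under the identical cross-validation
    protocol is included as the comparison classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
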