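Package: rwavenet
Title: R-Wave Detection in Surface EMG with a Supervised Convolutional
    Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts heart rhythm from single-channel surface
    electromyography (EMG) in which the electrocardiographic R-wave is
    embedded as a low-amplitude component. A supervised one-dimensional
    convolutional autoencoder maps fixed-length signal windows to binary
    R-wave masks; detected events are scored with an event-based
    precision/recall/F-measure protocol under pooled, leave-one-subject-out
    and per-subject cross-validation, and converted into a rhythmogram
    (R-R interval series) with basic heart-rate-variability statistics and
    tachycardia/bradycardia flags. A synthetic EMG+ECG mixture simulator
    with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
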