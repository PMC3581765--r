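Package: wristemg
Title: Wrist Kinematics Estimation from Multichannel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for simultaneous and proportional
    estimation of the three wrist degrees of freedom (flexion/extension,
    radial/ulnar deviation, pronation/supination) from multichannel forearm
    surface EMG. Provides conditioning of raw EMG (band-pass filtering,
    resampling, square-wave synchronization with motion capture), the
    Hudgins time-domain plus autoregressive (TDAR) feature set on sliding
    analysis windows, marker-based wrist joint-angle computation from seven
    anatomical markers, contralateral training of small multilayer
    perceptrons, and evaluation of intra- versus inter-arm-position
    generalization with the multivariate R-squared index and positional
    pooling. A fully parameterized synthetic-session generator emulates
    bilateral mirrored wrist movement recordings so that every stage of the
    pipeline is testable end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    nnet,
    purrr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
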