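Package: squeakseg
Title: Segmentation of Mouse Ultrasonic Vocalizations in Spectrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting mouse ultrasonic
    vocalizations (USVs, 30-110 kHz calls) in audio recordings. Computes
    Kaiser-window magnitude spectrograms from 250 kHz PCM WAV files, splits
    them into 50%-overlapping fixed-length chunks, labels each time frame
    with one of three small neural segmenters (a convolutional
    auto-encoder, a U-Net, and a convolutional-recurrent GRU network,
    trained with binary cross-entropy and Adam on a built-in reverse-mode
    autodiff core), cleans the predictions with one-dimensional binary
    closing and opening, and evaluates the result with frame-wise
    confusion metrics and intersection-over-union interval matching.
    A synthetic-call generator with exact ground truth makes every stage
    testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
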