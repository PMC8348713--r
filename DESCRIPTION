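Package: msceeg
Title: Multi-Scale Kernel Convolutional Networks for EEG-Based Emotion
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising affective state
    (valence/arousal) from multichannel EEG. Trials are decomposed into
    Theta, Alpha, Beta and Gamma bands with a high-order Butterworth
    filter bank realised in cascaded second-order sections, cut into
    non-overlapping segments, summarised by six time-domain features
    (differential entropy, mean, mean first/second difference, standard
    deviation, variance), arranged into 9x9 scalp-topographic grids tiled
    per band into an 18x18x6 feature tensor, and classified by a
    convolutional network whose blocks run parallel kernels of several
    sizes fused by a 1x1 convolution. Includes a synthetic EEG generator
    with band-limited oscillations, 1/f background noise and
    spatially-correlated electrodes so the whole pipeline is testable
    without access to licence-gated recordings, plus segment-level k-fold
    cross-validation and ablation harnesses over bands, kernel sets and
    segmentation start offsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse
Config/testthat/edition: 3
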