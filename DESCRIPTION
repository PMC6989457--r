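Package: foveanet
Title: Eccentricity-Dependent Networks for One-Shot Invariant Recognition
Version: 0.1.0
Authors@R: person("foveanet", "maintainers", email = "foveanet@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for studying intrinsic scale- and
    translation-invariance in one-shot recognition of novel glyphs. Implements
    a scale-channel, eccentricity-dependent neural network (multi-resolution
    centred crops of a simulated visual field with weight sharing and
    max-pooling over scales) alongside a matched single-resolution
    convolutional control, procedural glyph stimuli with scale/shift
    augmentation, supervised training, Pearson-correlation same/different
    metrics with accuracy-maximising thresholds and d-prime, and
    (size x eccentricity) invariance-window construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
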