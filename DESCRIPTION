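Package: emofuse
Title: Multimodal Emotion Recognition from EEG and Eye Tracking via
    Attentive Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-class emotion recognition from paired
    electroencephalography (EEG) and eye-tracking recordings. Implements a
    dual-branch spatio-temporal convolutional feature extractor (62-channel
    EEG and 4-channel pupil/gaze series), pupillary light-reflex removal by
    principal component analysis across participants, multi-scale feature
    fusion with cross-channel two-way soft attention, cross-entropy training
    with the Adam optimizer, stratified k-fold evaluation with macro
    precision/recall/F1 and Cohen's kappa, and a synthetic multimodal trial
    generator with controlled, complementary class structure for end-to-end
    testing without access to licensed recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
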