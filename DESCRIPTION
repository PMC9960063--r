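Package: gazeintent
Title: Visit-Intention Prediction from Eye-Tracking Gaze Data on Dynamic Web Layouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which areas of interest (AOIs) of a dynamic one-page
    web layout a user will fixate during future time windows, from eye-tracker
    gaze logs sampled at 120 Hz. Provides gaze/fixation/event log I/O with a
    dispersion-threshold (I-DT) fixation detector, AOI hit-testing that models
    scrolling, sticky components and an occluding pop-up, window segmentation
    with exact window-balanced user-to-fold assignment, three families of
    window features (AOI/component visit history, population-level AOI heat,
    gaze kinematics and oculomotor statistics), MLSMOTE multilabel
    oversampling, mutual-information multilabel feature selection, multilabel
    classifiers (binary relevance and classifier chains over ridge, kNN and
    SVM bases, plus ML-kNN), ranking and example-based evaluation metrics, and
    a semi-Markov synthetic browsing-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    e1071,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
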