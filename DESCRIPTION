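Package: postureval
Title: Validation and Misclassification Correction for Epoch-Level Posture Trackers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for validating thigh-worn posture trackers that report one
    activity label (sitting, standing, walking or idle) per 30-second epoch
    against a per-second reference stream. Harmonizes the two streams onto a
    common epoch grid with a dominance-plus-priority tie-break, derives
    analysis windows for standardized laboratory protocols, scores agreement
    with one-vs-rest sensitivity, specificity and predictive rates, and
    corrects detected activity-minute distributions for known
    misclassification via a reallocation estimator parameterized by a
    misallocation profile. Includes a seeded synthetic-data generator for
    laboratory sessions and free-living days so every pipeline stage can be
    exercised end to end without device exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
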