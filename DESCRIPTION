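Package: actispot
Title: Activity Spotting and Label Recommendation for Wrist-Worn
    Accelerometer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised labeling support for multimodal human-activity
    datasets recorded with wrist-worn inertial sensors.  From a handful of
    annotated intervals the package extracts signal templates, matches them
    against unlabeled accelerometer streams with (subsequence) dynamic time
    warping, selects top-k label candidates using an idle-baseline
    ("zeroline") filter or a temporal exclusion rule, clusters templates of
    complex activities by motion similarity, and evaluates recommendations
    against ground truth (temporal overlap, boundary offsets,
    candidate-to-label distances, recall, ROC).  Includes a seeded synthetic
    recording generator so every stage is testable without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    zoo,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
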