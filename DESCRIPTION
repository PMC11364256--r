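Package: openecho
Title: Open-Set View Classification and Quality Assessment for
    Ultrasound-Style Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for routine-view classification of short grayscale
    ultrasound-style videos, recognition of unknown views via logit-based
    anomaly scores with calibrated rejection thresholds, and view-quality
    prediction by sparse (L1-penalised) linear regression on time-averaged
    convolutional feature embeddings. A frame-level convolutional network is
    trained from scratch with group normalisation and AdamW; per-frame
    logits and penultimate features are averaged over time to the video
    level, and the maximum known-class logit serves as a familiarity score
    whose rejection threshold is calibrated on a validation set. Includes a
    full open-set evaluation suite (closed/full-set accuracy, balanced
    accuracy, one-vs-one and unknown-view ROC-AUC, OSCR curves and AUC,
    open-set confusion matrices, per-subcategory ROC) and a synthetic
    sector-fan phantom video generator with graded ground-truth quality and
    three unknown-view subcategories, so the entire pipeline is exercisable
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    png,
    withr
Config/testthat/edition: 3
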