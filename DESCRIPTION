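Package: stillsnet
Title: Automated Identification of Still's Murmur from Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary classification of pediatric
    heart-sound recordings as innocent Still's murmur (SM) versus potentially
    pathological murmur (PPM). Recordings are Butterworth bandpass filtered,
    segmented into cardiac cycles via a Shannon-energy lobe detector with
    explicit failure semantics (failed segmentation is classified PPM),
    featurized as fixed-size 55 x 129 decibel-normalized spectrograms, and
    classified per cycle by a small convolutional neural network trained with
    class-weighted cross-entropy; recording-level labels are obtained by
    majority vote. Includes a synthetic phonocardiogram generator with ground
    truth landmarks, five-fold stratified cross-validation, confusion-matrix
    metrics with SM as the positive class, and ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
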