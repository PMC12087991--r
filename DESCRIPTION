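Package: mealintake
Title: Dietary-Intake Estimation from Paired Before/After Meal Images with
    Multi-Task Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the fraction of a meal eaten and the food
    category from paired photographs taken before and after consumption, the
    workflow used for plate-waste assessment in hospital nutrition wards.
    Implements siamese feature extraction with late fusion and five head
    wirings (single-task, single-task with ground-truth category, multi-task,
    multi-task with inter-task connection, and its ground-truth-feedback
    variant), a bounded L1 regression loss combined with binary cross-entropy,
    Adam training with early stopping, paired data augmentation, stratified
    k-fold evaluation against a Comstock-style human-observer baseline, and
    Grad-CAM saliency maps. Ships a synthetic plate-scene simulator (white
    plate on a 2x2 cm checkerboard placemat) so the full pipeline can be
    exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
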