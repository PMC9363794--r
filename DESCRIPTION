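Package: dfameter
Title: Automated Disc-Fovea Angle Measurement from Fundus Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated measurement of the disc-fovea angle (DFA) in
    color fundus photographs. Segments the optic disc and a virtual macular
    area with lightweight encoder-decoder networks (DeepLabv3+ with a
    MobileNetV2 encoder, plus U-Net and PSPNet baselines) trained with a
    built-in CPU backpropagation engine, extracts region centers with the
    minimum enclosing circle of the largest connected component, and computes
    the signed angle between the disc-fovea line and the horizontal.
    Includes a seedable synthetic-fundus generator with exact ground-truth
    geometry, the full segmentation evaluation suite (per-class IoU and
    pixel accuracy, MIoU, MPA, center errors), and an end-to-end
    train/measure/evaluate pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
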