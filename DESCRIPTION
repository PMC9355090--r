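Package: SeedlingScreen
Title: Selective Screening of Plug-Tray Vegetable Seedlings from
    Side-View Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Image-analysis toolkit for deciding, seedling by seedling,
    whether a plug-tray vegetable seedling is healthy enough to
    transplant. Converts RGB captures to HSV, removes the background by
    color-threshold masking, and classifies each single-seedling image
    either by a rule-based screen on leaf and substrate pixel areas or
    by a three-class residual convolutional network trained on CPU.
    Includes confusion-matrix evaluation (per-class precision, recall,
    F1 and overall accuracy), a synthetic side-view seedling image
    generator with ground-truth areas and labels, and a frame-level
    pipeline that turns a multi-seedling capture into per-station
    keep/remove verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
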