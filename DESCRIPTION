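Package: cellcurator
Title: Feature-Based Curation of Bacterial Cell Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic quality control of single-cell detections from
    bacterial phase-contrast microscopy. Cell detections are represented
    as pole-to-pole coordinate meshes; the package converts between
    meshes and subpixel contours, extracts 26 morphological and
    intensity features per cell, supports a resumable good/bad/ambiguous
    labeling workflow, and trains, validates and deploys a support
    vector machine (with an optional Nystroem kernel approximation for
    large training sets) that separates trustworthy detections from
    segmentation artifacts. A seeded synthetic-scene generator renders
    rod-shaped cells with controlled detection defects so the whole
    pipeline can be exercised without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    zoo
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
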