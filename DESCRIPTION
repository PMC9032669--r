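Package: weedvision
Title: Crop and Weed Classification from Multi-Plant Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A vision pipeline for discriminating corn (crop), narrow-leaf
    weeds and broadleaf weeds in multi-plant field images taken at early
    growth stages. Vegetation is segmented from soil by HSV thresholding,
    cleaned by morphological opening and closing, and split into per-plant
    regions of interest by connected-component analysis. Each region is
    classified either by rotation-invariant uniform local binary pattern
    (LBP) texture histograms fed to a soft-margin support vector machine,
    or by a transfer-learning convolutional head trained on frozen backbone
    features. Includes a synthetic field-scene generator with ground truth
    for end-to-end evaluation, and accuracy/precision/recall/F1 reporting
    with confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    kernlab,
    jsonlite,
    yaml,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
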