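Package: popsparse
Title: Population Sparseness Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for population sparseness in two-photon
    calcium imaging of visual cortex. Covers rigid motion correction of
    fluorescence movies by normalized cross-correlation, response-based ROI
    segmentation from band-pass filtered differential images, delta-F/F0
    trace extraction with neuropil correction, half-maximum population and
    life-time sparseness statistics, shuffle-based ROC tests of single-trial
    response reliability, and nearest-centroid stimulus decoding with
    top-only / top-excluded response thresholding. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    tiff,
    igraph,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
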