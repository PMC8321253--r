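Package: mwiseg
Title: Unsupervised Tissue-Type Segmentation and Quality Metrics for
    Microwave Breast Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions two-dimensional reconstructed complex-permittivity
    images of the breast into tissue types (background, fatty, transition,
    fibroglandular, malignant) with an iterative k-means clustering scheme
    whose cluster count is selected automatically by two-sample
    Kolmogorov-Smirnov tests on the evolving tumor and tumor-complement value
    distributions.  Includes region-based and distance-based segmentation
    quality metrics (fidelity, dielectric cross-correlation, Dice, ratio of
    tumor detected, artefact rejection, average Hausdorff distance), a
    threshold-based baseline segmenter, a synthetic dielectric breast phantom
    generator with controllable degradations, and plain-text/PNG/JSON
    input-output helpers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
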