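Package: spheropick
Title: Spheroid Screening, Morphometrics and Transfer Planning for Brightfield Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational core of an automated spheroid screening-and-transfer
    workflow for brightfield microscopy. Generates seeded synthetic brightfield
    spheroid scenes with exact ground-truth instance masks (including defocus,
    illumination gradients and artifact classes such as air bubbles, plate
    borders and plastic defects), provides classical instance segmentation
    pipelines (Otsu and watershed) with shape filters and a pluggable segmenter
    registry, extracts per-object morphometric features in physical units
    (area, Crofton perimeter, circularity, equivalent diameter, solidity,
    sphere-equivalent volume), selects spheroids by criterion intervals,
    benchmarks instance segmentation with IoU-matched precision and sensitivity
    curves, and plans virtual plate scans and capillary transfers with Marlin
    G-code emission and transfer success-rate accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CellBasedAssays, Segmentation, Software, Visualization
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
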