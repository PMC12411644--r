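Package: polcontrast
Title: Signed Degree-of-Polarization Imaging and Tumor Contrast Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reflection-mode polarimetric imaging of tissue:
    Stokes-vector and signed circular/linear degree-of-polarization (DOP)
    images in which negative values encode helicity flipping and co-linear
    dominance, per-pixel Mueller-matrix reconstruction from a 16-state
    generator/analyzer scheme with beam-splitter correction,
    fluorescence-derived tumor masking with fiducial-based co-registration,
    and tumor versus non-tumor contrast statistics (unit-area histogram
    overlap, threshold-sweep ROC/AUC with bootstrap confidence intervals,
    region summaries). A seeded synthetic scene generator provides fully
    specified two-class test data so the whole pipeline is testable without
    animal imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
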