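Package: rodquant
Title: Single-Cell Morphometry, Growth and Z-Ring Quantification for
    Rod-Shaped Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for time-lapse microscopy of rod-shaped
    bacteria: segmentation of phase-contrast images, pill-mesh midline
    coordinate systems with length/width/spherocylinder-volume measurement,
    instantaneous single-cell growth rates, FtsZ-ring detection, scoring and
    spacing along the cell midline, adder cell-cycle statistics from tracked
    lineages, and optical-density growth-rate estimators for batch and
    plate-reader cultures.  Includes a synthetic-data generator that
    simulates adder-based growth and division with full ground truth and
    renders phase-contrast-like and fluorescence images, so that every stage
    of the pipeline is verifiable against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    mgcv,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
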