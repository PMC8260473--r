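Package: calcitrace
Title: Automated Calcium Transient Analysis for Cardiomyocyte Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of calcium-indicator fluorescence recordings of
    paced cardiomyocytes: cell segmentation of multi-frame image stacks, per-cell
    fluorescence trace extraction with background subtraction, photobleach and
    baseline-drift correction by polynomial detrending, transient segmentation by
    difference-array onset detection, kinetic parameter estimation (tau, rise and
    decay times, amplitude ratios) from averaged or per-beat transients, detection
    and classification of irregular beats (pacing non-adherence, early and delayed
    afterdepolarization-like events), ratiometric (Fura-2 style) calibration to
    absolute calcium concentration, and a fully seeded synthetic-data generator
    with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    readxl,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
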