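Package: coloctools
Title: Per-Cell Colocalization Analysis for Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless pipeline for visualizing and measuring colocalization of
    two or three reporters in cells and whole organisms. Provides cell
    identification (auto-thresholding, watershed segmentation, border removal,
    physical and signal-intensity cell filters), threshold-based image
    alignment, top-percentile (F_T) pixel selection, colocalization metrics
    (threshold overlap score with linear or logarithmic scaling, Pearson and
    Spearman correlation, intensity correlation quotient, Manders'
    coefficients, Costes' automatic thresholds), metric matrices over
    threshold grids, heat maps, scatterplot data, per-cell data tables, and a
    seeded synthetic-image generator with ground truth. Reads and writes
    grayscale TIFF stacks, binary masks, and ImageJ ROI sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    zip
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
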