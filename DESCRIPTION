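Package: blotgrid
Title: Spot-Grid Densitometry and Differential Expression for Membrane
    Cytokine Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic analysis of scanned dot-blot antibody (cytokine)
    membrane arrays: Gaussian-blur preprocessing and local-maxima detection,
    corner-anchored bilinear grid interpolation with block alleyways and
    maxima snapping, integrated spot densitometry, quantile-curve spline
    normalization, background-based detection calls, empirical-Bayes
    moderated-t differential expression with Benjamini-Hochberg FDR and
    composite up/down criteria, and cross-series / cross-gender consensus
    biomarker panels. Includes a synthetic membrane simulator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    ape,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
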