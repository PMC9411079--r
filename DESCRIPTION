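Package: dqcentroid
Title: Centroiding of High-Resolution Profile Mass Spectra with Data
    Quality Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts profile-mode high-resolution mass spectra (mzML or
    mzXML) into centroid tables while preserving peak width, area and a
    per-centroid Data Quality Score (DQS). Peak profiles are isolated by
    zero-intensity boundaries and valley splitting, fitted with a
    log-linearized weighted Gaussian regression (Caruana's second-order
    polynomial), and the propagated uncertainty of the Gaussian peak area
    is mapped through the error function to a score in [0, 1]. Includes a
    synthetic spectrum generator with an Orbitrap-like resolution model
    for validation, mass-resolution power-law fitting, and cross-scan
    centroid grouping for m/z precision studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mzR,
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
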