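Package: dcedro
Title: Digital Reference Objects for Validating DCE-MRI Kinetic Model Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates customizable digital reference objects (DROs) for
    dynamic contrast-enhanced MRI (DCE-MRI) kinetic-model analysis software
    validation. Known kinetic parameters (Tofts, extended Tofts, Patlak,
    tissue-uptake and two-compartment exchange models, plus user plug-ins)
    are pushed through a forward pipeline: residue-function convolution with
    a plasma arterial input function, the spoiled gradient-echo (SPGR)
    signal equation with B1-corrected flip angles, and export as DICOM
    series with T1,0/R1,0, B1, variable-flip-angle and ground-truth
    parameter maps. A self-validation module inverts the pipeline
    (signal-to-concentration conversion, bounded nonlinear least-squares
    fitting, variable-flip-angle T1 estimation) and scores agreement of
    fitted against true parameters with Lin's concordance correlation
    coefficient and 95% confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
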