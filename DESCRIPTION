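Package: degtrace
Title: Quantification and Kinetics of Acute Protein Degradation in
    Fluorescence Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify punctate synaptic fluorescence in
    multi-channel time-lapse movies and longitudinal in-vivo z-stack
    sessions, and to fit degradation kinetics of degron-tagged proteins.
    Includes punctum detection and tracking with 9x9-pixel ROI
    quantification on maximum-intensity projections, background
    correction and spectral unmixing, a grid-search biexponential decay
    fitter with major/minor pool reporting, initial-rate and per-synapse
    correlation analyses, a nuclear-reference ring-quantification
    pipeline for longitudinal in-vivo imaging, and a seeded synthetic
    microscopy generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    jsonlite,
    yaml,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
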