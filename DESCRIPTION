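Package: galQuant
Title: Quantitative alpha-Gal Antigen Determination by M86 ELISA Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a standardized quantitative workflow for remnant
    alpha-Gal xenoantigen determination in animal tissues and tissue-derived
    biomaterials from raw 96-well OD450 readings of an M86 ELISA inhibition
    assay. Covers inhibition-rate computation, exponential-saturation
    standard-curve fitting and inverse prediction against a Gal-BSA
    calibration series, IC50 and lower-detection-limit determination,
    conversion of Gal-BSA-equivalent mass to epitope counts per reaction,
    per mg tissue or per cell, reference-material QC gates (specificity,
    accuracy, homogeneity, stability) and repeatability statistics, plus a
    synthetic plate simulator for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
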