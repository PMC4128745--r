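Package: phagechar
Title: Quantitative Characterization of Lytic Bacteriophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimators and simulators for the standard quantitative assays
    used to characterize lytic bacteriophages as therapeutic candidates:
    adsorption kinetics (Adams rate constant), one-step growth analysis
    (latent period and burst size), efficiency of plating and host-range
    matrices, phage-resistant mutant frequency, Appelmans serial-dilution
    broth assays (MOI design, lysis endpoints, cocktail comparisons), and
    in silico restriction-fragment fingerprinting with band-matching
    similarity and neighbor-joining dendrograms. A synthetic assay-data
    generator reproduces the statistical structure of every assay so each
    estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings,
    IRanges,
    deSolve,
    minpack.lm
Suggests:
    withr,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
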