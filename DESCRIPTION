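Package: sensarray
Title: Simulation and Pattern Recognition for Supramolecular
    Indicator-Displacement Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico modelling of supramolecular chemical-nose sensor
    arrays built on the indicator displacement assay. Solves coupled 1:1
    host-guest competitive binding equilibria for arbitrary panels of
    receptors, reporter dyes and analytes, maps speciation to fluorescence
    observables (I/I0 response ratios, direct and competitive titration
    curves), constructs sensor arrays under five construction strategies
    (reporter-pair replacement, dye replacement, coassembly ratio, reporter
    pair ratio, environmental condition), generates noisy replicate response
    matrices, and performs from-scratch Fisher linear discriminant analysis
    with canonical scores, jackknifed (leave-one-out) classification, 95
    percent confidence ellipses, maximal discriminable analyte subsets and
    pairwise array-combination screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
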