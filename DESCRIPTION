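Package: lysoSPAR
Title: Structure-Property-Activity Modelling of Functional Acid
    Sphingomyelinase Inhibition by Lysosomotropic Drugs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to identify functional inhibitors of acid
    sphingomyelinase (FIASMAs) from physicochemical compound data.
    Implements derived and count-based molecular descriptors, a
    Fick-Nernst-Planck compartment model of lysosomal ion trapping,
    random-forest classification of functional inhibition with
    beam-search descriptor selection, bootstrap and response-permutation
    (Y-scrambling) validation, a Tanimoto-fingerprint relative
    structural diversity statistic, and virtual-screening enrichment
    analysis over therapeutic drug groups. A synthetic-data generator
    emulating the statistical structure of cell-based residual-activity
    assays makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    deSolve,
    igraph,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
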