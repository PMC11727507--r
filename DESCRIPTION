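Package: inbload
Title: Pedigree-Based Estimation of Individual Inbreeding Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes pedigree inbreeding into per-ancestor partial
    inbreeding coefficients by the Mendelian (tabular) decomposition, builds
    the sparse load design matrix K = T(I-P) linking phenotyped animals to the
    inbreeding-load effects of their ancestors, and fits a bivariate
    repeatability animal model by restricted maximum likelihood in which the
    additive genetic effect and the inbreeding load share the pedigree
    relationship matrix. Includes the single-locus theory that grounds the
    inbreeding load as an additive effect of ancestors, a likelihood-ratio
    test of the load variance against a boundary-mixture null, a synthetic
    pedigree and phenotype generator for validation studies, and a small
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
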