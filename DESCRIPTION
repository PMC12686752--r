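Package: mbssgblup
Title: Multi-Breed Single-Step Genomic Evaluation with LR Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single- and multi-breed genetic evaluation of
    performance-test traits in beef cattle: pedigree relationship matrices
    (including metafounders), genomic relationship matrices (VanRaden method 1,
    breed-wise scaling, 0.5-frequency base), single-step H-inverse assembly,
    single- and multi-trait mixed-model equations, Gibbs-sampling variance
    component estimation, forward-in-time LR validation of breeding values
    (accuracy, dispersion and level bias with bootstrap standard errors), and a
    gene-dropping simulator of multi-breed performance-test datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
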