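Package: thermsol
Title: Thermal Proteome and Solubility Profiling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of multiplexed proteomics experiments that
    probe ligand-induced changes in protein thermal stability and solubility.
    Implements dose-response (four-parameter logistic) model fitting with an
    intercept null model, sliding temperature-window F-statistics for
    two-dimensional thermal proteome profiling (2D-TPP), a stratified
    permutation-based false discovery rate, pEC50 assignment, solubility
    proteome profiling (SPP) normalization and insoluble-proteome
    classification, melting-curve fitting with melting-point (Tm) extraction,
    and protein-complex co-melting analysis with a randomization test.
    Includes generators for synthetic TPP-TR, 2D-TPP and SPP datasets with
    known ground truth so the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    MASS,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
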