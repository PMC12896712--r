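Package: crosspopgs
Title: Cross-Population Genomic Prediction with Fst-Screened Reference Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of livestock populations with
    distinct linkage-disequilibrium histories, Weir-Cockerham fixation-index
    screening of differentiated markers, Euclidean-distance selection of
    genetically similar individuals, and construction of stratified
    cross-population reference sets for genomic prediction. Breeding values
    are predicted by pedigree BLUP, GBLUP, single-step GBLUP (H matrix) and
    SNP-window-weighted GBLUP solved through Henderson's mixed-model
    equations, with EM-REML variance estimation and accuracy/dispersion-bias
    scoring against simulated true breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
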