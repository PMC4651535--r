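Package: interspat
Title: Pairwise Interspecific Spatial Associations in Mapped Forest Stands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Second-order point-pattern analysis of interspecific spatial
    associations in stem-mapped forest censuses. Implements the bivariate
    (intertype) L-type function and an intertype mark-correlation function
    for diameter marks, Monte Carlo null models (toroidal shift and random
    marking) with pointwise quantile envelopes and quasi p-values,
    standardisation and pooling of replicate plots onto a common [-1, 1]
    null band, and summaries of detected associations: signed association
    matrices, guild cross-tabulations and habitat-concordance counts. A
    synthetic-stand generator with known ground truth (Thomas clusters,
    linked clusters, hardcore repulsion, cohort and nursery mark structure)
    supports end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
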