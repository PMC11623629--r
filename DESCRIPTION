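Package: repgeom
Title: Representational Geometry Analysis for Condition-Rich Neuroimaging
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representational similarity analysis (RSA) of
    condition-rich event-related experiments: serially counterbalanced,
    efficiency-optimized trial sequence and onset generation; behavioral
    multiple-arrangement subset design and sparse-distance aggregation into
    representational dissimilarity matrices (RDMs); gaze-trajectory
    preprocessing and gaze RDMs with reliability screening; semantic
    embedding and generic feature RDMs; split-data (cross-session) neural
    RDMs; per-model rank-correlation fits, rank-standardized joint
    regression, variance partitioning via full-versus-nested regression,
    and intersubject-correlation noise ceilings; sign-flip permutation,
    re-centered bootstrap, condition-label permutation, and bootstrap
    confidence intervals with false-discovery-rate control; and a
    synthetic-data generator with planted ground truth for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
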