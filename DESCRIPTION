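Package: crosslight
Title: Cross-Participant Searchlight RSA and Decoding for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encoding-based representational similarity analysis (RSA) and
    multivariate decoding in searchlight form, cross-validated across
    participants, for fMRI studies of conscious and unconscious visual
    perception. Provides voxelwise ridge encoding models mapping stimulus
    features to BOLD responses, representational dissimilarity matrices
    (1 - Pearson) compared by Spearman correlation, an L1-regularized linear
    support-vector-machine decoder scored by ROC AUC, a generic searchlight
    engine, and group-level inference by threshold-free cluster enhancement
    (TFCE) with sign-flip max-statistic permutation testing. A synthetic-data
    generator plants known representational structure in small 4D volumes so
    that every stage of the pipeline has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    png,
    withr
Config/testthat/edition: 3
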