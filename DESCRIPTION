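Package: icapr
Title: Dynamic Functional Connectivity via Innovation-Driven Coactivation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for dynamic functional connectivity analysis
    of paired-session resting-state fMRI using innovation-driven coactivation
    patterns (iCAPs). Provides voxel-wise hemodynamically informed sparse
    deconvolution (total-activation style, FISTA with a total-variation
    proximal step), selection and temporal k-means clustering of transient
    frames with consensus-based choice of the number of networks, extraction
    of temporal properties (total duration, occurrences, Jaccard coupling and
    anticoupling), reliable change indices, group and pre/post statistics with
    false-discovery-rate control, and partial least-squares correlation with
    permutation significance testing and bootstrap loading stability. A
    synthetic-data module generates paired-session cohorts with planted
    network activations and clinical change scores for validation with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    lme4,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
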