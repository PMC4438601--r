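Package: swnet
Title: Small-World Graph Analysis of Resting-State Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds weighted, undirected functional connectivity networks
    from regional BOLD time series and quantifies treatment-related change
    in network topology. Provides temporal preprocessing (volume discard,
    band-pass filtering, nuisance regression, DVARS quality control),
    shrinkage-regularized partial-correlation network estimation,
    proportional sparsity thresholding with weighted graph metrics
    (clustering, path length, efficiency, modularity, betweenness)
    normalized against degree-preserving random networks, sparsity-AUC
    aggregation with motion residualization, paired change tests with a
    permutation fallback, covariate-adjusted prediction of follow-up
    symptom change, and a seeded synthetic-cohort generator with planted
    modular network structure and clinical trajectories for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    signal,
    RNifti,
    jsonlite,
    yaml,
    pracma,
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
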