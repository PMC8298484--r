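Package: CircaTemp
Title: Circadian Wrist Temperature Rhythm Profiling and Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for data-driven profiling of circadian rhythms in
    minute-resolution wrist skin temperature recordings from free-living
    cohorts. Provides a synthetic cohort generator with cluster-structured
    cosinor parameters, start-time harmonization to a common 48-hour noon
    window, regularized iterative principal-components imputation, loess and
    smoothing-spline smoothing with a smoother-sensitivity exclusion rule,
    single-component cosinor fitting with iterative period estimation and
    quadrant-corrected acrophase, k-medoids clustering of discrete Fourier
    features with validity indices (silhouette, Dunn, Davies-Bouldin,
    eigenvalue-based RMSEA/eBIC analogues) and t-SNE/network stability
    diagnostics, actigraphy-style sleep summaries with delayed sleep phase
    classification and a six-item morningness-eveningness sum score, and
    bias-corrected bootstrap association analyses with Benjamini-Hochberg
    false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    mclust,
    igraph,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
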