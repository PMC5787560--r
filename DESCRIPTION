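Package: mbtime
Title: Analysis of Longitudinal Microbiome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for longitudinal microbiome abundance tables:
    QIIME-classic and plain TSV ingestion with taxonomic aggregation,
    relative and rarefaction normalization with rarefaction curves,
    richness and Shannon diversity, core/persistent/transient prevalence
    classification, per-taxon augmented Dickey-Fuller stationarity screening,
    temporal-shape comparison via band-constrained dynamic time warping and a
    bounded mirror-normalized DTW distance, Pearson and DTW hierarchical
    clustering with Newick export, pairwise Granger and Granger-Lasso
    causality network inference, two-window Wilcoxon differential abundance,
    and Jensen-Shannon divergence community-state typing by K-medoids.
    Includes seeded synthetic-data generators with planted causal, unit-root,
    shape-group and community-state structure, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    cluster,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
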