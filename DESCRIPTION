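Package: acuteomix
Title: Integrative Multi-Omics Analysis of Acute Exercise Response in Skeletal Muscle
Version: 0.1.0
Authors@R:
    person("acuteomix", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of an integrative multi-omics
    analysis pipeline for acute exercise studies in skeletal muscle. Provides
    ome-specific preprocessing (filtering, TMM/log-CPM normalization, imputation,
    PCA outlier flagging, batch residualization), per-feature difference-in-changes
    mixed models with precision weights and empirical-Bayes moderation, enrichment
    statistics (CAMERA-PR, hypergeometric over-representation, directional PTM
    signature enrichment), pathway-guided cross-omic latent-variable decomposition,
    phospho-TF regulatory network inference with tree-ensemble importances,
    permutation trimming, simplified cis-regulatory circuit linking and network
    motif scores, nearest-neighbor phosphosite analysis, and MCL-based merging of
    CpG sites into regions. A synthetic-cohort generator with planted ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    optparse
Config/testthat/edition: 3
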