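Package: amlsubtypes
Title: Multi-Cohort Expression Subtype Discovery and Drug Prioritization
    for NPM1-Mutated AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for discovering expression subtypes of
    NPM1-mutated acute myeloid leukemia across independent patient cohorts
    and prioritizing drugs against them. Provides per-cohort consensus
    K-medoids clustering with silhouette-based model selection,
    meta-clustering of cohort clusters through a centroid-correlation
    network with label-propagation community detection, fixed-effect
    inverse-variance meta-analysis of per-cohort log fold changes,
    elastic-net transfer of subtype labels to a cell-line panel,
    Hill-equation dose-response fitting with closed-form normalized AUC,
    concordance-index drug ranking with a permutation null, and the
    survival and mutation-association statistics used to characterize the
    subtypes. A negative-binomial multi-cohort simulator with planted
    ground truth makes every stage testable without access-controlled
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    igraph,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
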