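Package: morbclust
Title: Disease-Driven Multimorbidity Clustering from Primary-Care Chapter Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies clusters of multimorbidity from chapter-level primary-care
    morbidity records. For every pair of diagnostic chapters the Jaccard
    co-occurrence index (the probability of holding records in both chapters
    given a record in at least one) is estimated by union-restricted
    random-intercept logistic regression with followup time, age at first
    record, sex and exposure (eczema or asthma) as covariates, then predicted
    at standardized population profiles. Predicted indices feed thresholded
    undirected chapter networks and agglomerative hierarchical clustering
    (complete linkage, with Ward linkage as a sensitivity option). A synthetic
    electronic-health-record generator with practice-level clustering, a
    Gaussian-copula dependence structure and validated-style eczema/asthma
    case algorithms supplies reproducible inputs in place of licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
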