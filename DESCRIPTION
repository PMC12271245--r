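Package: genevec
Title: Gene-Vector Diversity and Constrained Neural-Net Prediction of
    Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes within-gene SNP genotypes as base-3 "gene vectors",
    quantifies genotypic-pattern diversity (diversity indices, departures
    from SNP independence, between-gene pattern co-occurrence), derives
    clinical response and onset-of-improvement labels from repeated
    HAM-D17/PANSS scale scores, screens genes for response-characteristic
    genotypic patterns, and trains a constrained multilayer sigmoid
    network (online backpropagation, 10-fold cross-validation, random-walk
    restarts, greedy classifier-gene selection) to separate treatment
    responders from non-responders.  Ships a synthetic-cohort generator
    that reproduces the statistical structure of a two-diagnosis
    psychiatric inpatient study (Hardy-Weinberg genotypes with
    within-gene dependence, planted response genes, trigger-model score
    trajectories, elevated-IgM flags) so that every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
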