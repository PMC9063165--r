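Package: adbalance
Title: Compositional Balance Models for Gut-Microbiome Discrimination of
    Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discriminating amyloid-positive
    Alzheimer's disease (AD) patients from healthy controls using shotgun
    metagenomic abundance tables (genera, Gene Ontology terms, KEGG
    orthologs) and clinical covariates. Implements hits-per-million
    normalisation, compositional log-ratio transforms (clr/ilr) and
    balances, Wilcoxon pre-selection with backward feature shrinkage under
    repeated stratified cross-validation, logistic block models stacked
    into an ensemble, ROC/AUROC evaluation with confidence intervals,
    cohort group comparisons including a Hotelling T-squared
    covariate-influence test on principal components of ilr-transformed
    genera, effect summaries as differences of logarithmised medians, and
    a synthetic case-control cohort generator for end-to-end testing
    without access to raw sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    generics,
    pROC,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
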