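Package: methylscore
Title: DNA Methylation Regulator Subtyping and Prognostic Scoring for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers DNA 5-methylcytosine (5mC) regulator expression subtypes in
    tumor cohorts by resampling-based consensus clustering with partitioning
    around medoids, derives subtype differentially expressed genes with
    empirical-Bayes moderated t-statistics, builds a PCA-based DNA methylation
    score (DMS) from prognostic genes screened by univariate Cox regression,
    stratifies survival at a maximally selected log-rank cutpoint, and runs
    gene-set enrichment (weighted Kolmogorov-Smirnov GSEA, hypergeometric
    over-representation, per-sample signature scores). Ships a synthetic-cohort
    generator with planted cluster, differential-expression and survival
    structure so the whole pipeline is testable offline.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    fgsea,
    jsonlite,
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
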