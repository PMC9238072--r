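Package: hearload
Title: Gene-Level Variant Load Analysis for Self-Reported Hearing Difficulty Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exome-wide variant load analysis toolkit for case-control
    cohorts phenotyped by questionnaire, built around self-reported hearing
    difficulty in older adults. Provides longitudinal phenotype grouping,
    variant call quality control, predicted-impact and allele-frequency
    classification of annotated variants, per-gene variant load regression
    with interquartile-range residual outlier detection, hypergeometric
    gene-list enrichment with Bonferroni adjustment, minor-allele-frequency
    weighted burden testing with signed log p ranking, and inner-ear
    expression panel scaling and clustering. A synthetic cohort generator
    with known spiked signal makes the whole pipeline testable without
    access to controlled cohort data.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    readr,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
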