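# hearload

Gene-level variant load analysis for exome-sequenced cohorts phenotyped
by questionnaire, built around self-reported hearing difficulty in older
adults.

Age-related hearing loss is common and strongly genetic, but family
studies only see ultra-rare high-impact variants and GWAS only see
common markers. hearload implements an aggregate approach that can pick
up intermediate-frequency signal: per gene *g*, sum the qualifying
variant alleles carried by the hearing-difficulty group
(y<sub>g</sub>) and by the normal-hearing group (x<sub>g</sub>), fit
ordinary least squares across all genes,

    y_g = a + b * x_g + r_g ,

and call a gene an outlier when its residual r<sub>g</sub> falls
outside the interquartile band of the residual distribution:

    r_g > Q3 + 6 (Q3 - Q1)   (high load in hearing difficulty)
    r_g < Q1 - 6 (Q3 - Q1)   (high load in normal hearing)

Outlier lists are screened against curated gene lists with upper-tail
hypergeometric tests (Bonferroni-adjusted, family size always
recorded), complemented by a MAF-weighted per-subject burden test
ranked by signed log p (SLP), and by inner-ear expression profiles
(reference-gene normalisation, per-cell-type max collapse, piecewise
log scaling, variance filtering and hierarchical clustering).

The package covers the full pipeline:

| stage | functions |
|---|---|
| phenotype grouping | `classify_hearing()`, `summarize_groups()` |
| variant QC | `qc_config()`, `mask_calls()`, `site_qc()`, `excess_heterozygosity()` |
| impact / frequency filters | `classify_impact()`, `max_external_maf()`, `select_variants()` |
| load regression + outliers | `per_gene_load()`, `fit_load_regression()`, `detect_outliers()`, `stratified_load_outliers()`, `summarize_variant_types()` |
| enrichment | `hypergeom_tail()`, `enrich()`, `overlap_partition()` |
| weighted burden | `burden_config()`, `variant_weight()`, `subject_gene_scores()`, `burden_test()`, `rank_by_slp()` |
| expression | `normalize_to_reference()`, `collapse_max()`, `scale_levels()`, `variance_filter()`, `cluster_genes()`, `describe_clusters()` |
| orchestration | `study_config()`, `run_study()` |
| synthetic data | `sim_config()`, `simulate_cohort()`, `simulate_variants()`, `simulate_gene_lists()`, `simulate_expression_panel()` |

Results are tibbles (or small S3 objects with `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures), so stages chain with the
pipe. I/O helpers read and write plain-text VCF, TSV cohorts, one-gene-
per-line lists and gene x cell-type expression tables.

## Worked example

A synthetic cohort with known ground truth: 500 participants, 400
genes, 10 genes spiked 3-fold on high-impact variants in the
hearing-difficulty group.

```r
library(hearload)

cfg <- sim_config(n_participants = 500, n_genes = 400, n_spiked = 10,
                  deafness_list_size = 60, variable_list_size = 40,
                  seed = 2024)
cohort <- simulate_cohort(cfg)
calls  <- classify_hearing(cohort, min_age = 55)
table(calls$group)
#> difficulty   excluded     normal
#>        245         31        224
```

245 participants report consistent or worsening difficulty (or aid
use), 224 qualify as normal hearing, and 31 are excluded (implants,
otologic disorders, reversals, tinnitus/noise screens).

```r
sim  <- simulate_variants(cfg, cohort)
geno <- mask_calls(sim$geno)                    # DP/GQ < 10 -> missing
qc   <- site_qc(sim$variants, geno)             # QUAL/missing/AF/HWE
v    <- sim$variants |> add_max_external_maf() |> classify_impact() |>
  select_variants("high", maf_cutoff = 0.1, qc = qc)

out <- per_gene_load(v, geno, calls, universe = cfg$gene_universe) |>
  fit_load_regression() |>
  detect_outliers(multiplier = 6)
out
#> <outlier_result> 400 genes; Q1 = -18.985, Q3 = 5.711, D = 24.696
#>   8 outliers with high load in hearing difficulty, 0 with high load in normal hearing
```

Eight genes exceed the Q3 + 6D threshold; all eight are spiked genes
(8 of the 10 planted; the two missed ones carry too little common
high-impact variation to clear the threshold at this cohort size). The
synthetic "deafness" list contains every spiked gene plus decoys, so
the case-side outlier list should enrich strongly:

```r
lists <- simulate_gene_lists(cfg)
enrich(out$outliers_case, lists$lists$deafness, lists$universe, m = 4)
#> # A tibble: 1 × 7
#>       N     K     n     k       p_raw       p_adj     m
#>   <int> <int> <int> <int>       <dbl>       <dbl> <int>
#> 1   400    60     8     8 0.000000169 0.000000676     4
```

All 8 outliers are "deafness" genes (k = n = 8); the adjusted
hypergeometric p is 6.8e-7 with the Bonferroni family size m = 4
recorded beside it. The weighted burden test ranks the same genes at
the top by SLP:

```r
ranking <- rank_by_slp(burden_test(subject_gene_scores(v, geno), calls))
head(ranking$ranked[, c("gene_id", "mean_case", "mean_control", "p", "slp")], 3)
#> # A tibble: 3 × 5
#>   gene_id mean_case mean_control        p   slp
#>   <chr>       <dbl>        <dbl>    <dbl> <dbl>
#> 1 G00313       15.0         4.24 4.83e-42  41.3
#> 2 G00370       14.5         4.95 6.67e-36  35.2
#> 3 G00119       14.8         4.96 1.22e-34  33.9
```

A positive SLP (= -log10 p signed by the case-control mean difference)
means cases carry more weighted burden. `run_study()` wraps all of the
above over a grid of impact levels, MAF cutoffs and sex strata and
returns a tidy per-cell report.

## Vignette

`vignettes/variant-load-analysis.Rmd` documents the model and its
assumptions, every tunable threshold with its default and rationale,
what the synthetic generator does and does not emulate, numerical
choices and known limitations.
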