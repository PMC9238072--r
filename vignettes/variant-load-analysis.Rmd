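---
title: "Gene-level variant load analysis of self-reported hearing difficulty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level variant load analysis of self-reported hearing difficulty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearload)
```

## The problem

Age-related hearing loss is common, heterogeneous and strongly genetic,
but most of its genes are unknown. Family studies find ultra-rare
high-impact variants; genome-wide association studies find common
markers; variants of intermediate frequency are hard to interrogate with
either design. hearload implements an aggregate, gene-level approach for
exome-sequenced cohorts phenotyped by questionnaire: per gene, sum the
qualifying variant alleles carried by each phenotype group, regress the
case-group load on the control-group load across all genes, and call a
gene an outlier when its residual falls far outside the bulk of the
residual distribution. Outlier lists are then screened for biological
plausibility against curated gene lists (known deafness genes, and genes
that are noisy in exome data generally), complemented by a per-subject
weighted burden test and by inner-ear expression profiles of the
candidate genes.

The package is organised as a set of tidyverse-style functions, one per
analysis stage, plus `run_study()` which executes the full grid of
impact level x allele-frequency cutoff x sex stratum cells. A synthetic
data module generates every input with known ground truth, so the whole
pipeline is testable without access to any controlled cohort data.

## Phenotype grouping

`classify_hearing()` assigns each participant to `normal`, `difficulty`
or `excluded` from longitudinal questionnaire answers. The rules, and
the readings we chose where the wording of self-report rules is
genuinely open:

- A *difficulty report* at a visit is a "yes" to either the hearing
  difficulty question or the difficulty-in-noise question. A "no"
  requires a concrete no with no yes at that visit; everything else is
  unknown.
- *Consistent or worsening* is read strictly: yes at every visit where
  the question was answered, or a no-to-yes transition with no later
  reversal. Any yes-to-no reversal without hearing aid use excludes the
  participant rather than counting as difficulty; aid use at any visit
  is difficulty evidence on its own.
- *Asked at the qualifying age* means at least one visit at or above
  `min_age` (default 55 years) with a non-unknown difficulty answer.
- Unknown answers are ignored, but a participant with no concrete
  answer at all is excluded: silence is never classified as normal
  hearing.
- Cochlear implant use and otologic disorders exclude from both groups.
  High noise exposure and moderate or severe tinnitus exclude only from
  the normal group; they are screens against undetected hearing damage,
  not difficulty evidence.

Exclusion reasons are coded (`cochlear_implant`, `otologic_disorder`,
`not_asked_at_min_age`, `difficulty_reversal`, `noise_exposure`,
`tinnitus_moderate_or_severe`, `no_concrete_answer`), with the checks
applied in that order, so group counts can be audited rule by rule.

## Variant quality control

Thresholds live in `qc_config()`. The defaults: site quality QUAL >= 20;
per-call read depth DP >= 10 and genotype quality GQ >= 10 ("minimum" is
read as inclusive); at most 10% missing calls per site; a private-allele
screen failing sites whose cohort alternate-allele frequency exceeds the
maximum external minor allele frequency plus 0.4; and an excess
heterozygosity filter.

Two design points deserve note:

- DP/GQ failures are applied to *calls*, not sites: `mask_calls()` turns
  them into missing genotypes, which then count toward the 10%
  missingness rule in `site_qc()`. Reasons are recorded as the first
  failing rule in the order qual, missingness, private AF, excess
  heterozygosity.
- The heterozygosity filter combines excess heterozygosity
  (O - E)/E > 0.1 (with E = 2pqN at the observed allele frequencies)
  with a Hardy-Weinberg test rejection. The flavour of the test and its
  level are open choices; we use the exact conditional test (summing
  the probabilities, given the allele counts, of all heterozygote counts
  no more likely than the observed one), computed in log space, with
  alpha = 0.05. The conjunction keeps the filter conservative whichever
  convention a comparison dataset used. The implementation is verified
  against full enumeration in the test suite.

External allele frequencies are folded to the minor allele and the
maximum across populations is used (`max_external_maf()`); a variant
with no reported frequency is treated as novel (MAF 0), which keeps
novel variants inside every frequency cutoff.

## Impact classification

Two inclusive tiers (`classify_impact()`), all inequalities strict:

- **High**: coding, splice-site or mature-miRNA variants with CADD > 25
  or SpliceAI > 0.5; 5' UTR variants with Sutr > 1 (CADD is not
  consulted for UTRs).
- **Low**: every high-impact variant; all coding, splice, miRNA, 5' UTR
  and 3' UTR variants; and variants of any other class (regulatory,
  intronic, intergenic) rescued by ReMM > 0.95. 3' UTR variants are
  unconditionally low impact and never high.

A variant annotated with several consequence terms is classified by its
most severe term, using the severity order in
`consequence_vocabulary()`. In MSC mode a per-gene CADD cutoff table
replaces the fixed 25; genes without a cutoff are dropped from that
analysis rather than silently falling back to the fixed threshold.

## Load regression and outlier rule

`per_gene_load()` sums, per gene, the alternate alleles carried by each
phenotype group (a homozygote counts 2); missing calls contribute 0.
Counting carriers instead of alleles is available via `counting_mode`
because aggregate "numbers of variants" can be read either way — both
modes are tested, alleles is the default. Genes with no surviving
variants are retained as (0, 0) rows: they are part of the gene universe
and anchor the regression intercept. No group-size normalisation is
applied by default, matching the aggregate design even for unequal
sex-stratified groups; a per-capita reading is available by dividing
loads by the group sizes stored as attributes.

`fit_load_regression()` is ordinary least squares of case load on
control load, with intercept, computed from the closed-form normal
equations (and checked against `lm()` to 1e-10 in the tests). The
per-gene residual is observed minus predicted case load.
`detect_outliers()` computes the residual quartiles Q1 and Q3 and
D = Q3 - Q1 and flags genes with residuals strictly above Q3 + 6D
(high load in hearing difficulty) or strictly below Q1 - 6D (high load
in normal hearing). The quantile convention is type 7, R's default
linear interpolation, and is configurable because published analyses
rarely state it. With D = 0 (more than half the genes on the fitted
line) the thresholds collapse onto the quartiles and any nonzero
residual on the right side is an outlier; this degenerate case is
exercised in the tests.

`stratified_load_outliers()` repeats the analysis per sex stratum;
loads are additive across strata by construction, which the tests
assert.

## Enrichment

`hypergeom_tail()` computes the upper-tail probability P(X >= k) of the
hypergeometric distribution directly in log space (log-binomial
coefficients combined by log-sum-exp), exact-enumeration-checked for
every small universe in the tests. `enrich()` intersects query and
reference with the gene universe (dropping strays with a warning) and
applies a Bonferroni correction. Because the family size behind any
published adjusted p is easy to lose, `m` is always recorded next to
the adjusted value; `run_study()` uses one family spanning every cell x
direction x reference list it runs. `overlap_partition()` produces the
disjoint Venn regions of two or three outlier lists with per-region
membership and reference-gene flags.

## Weighted burden test

`subject_gene_scores()` gives each subject, per gene, the weighted sum
of their alternate allele counts. The weighting direction — rarer
variants weigh more — is standard for this family of tests, but the
exact functional form used by any given tool is rarely printed, so we
use a transparent linear ramp, w = 1 + (W - 1)(cap - MAF)/cap, from
W = 10 at MAF 0 down to 1 at the analysis MAF cap; both W and the form
are configurable in `burden_config()`. `burden_test()` compares mean
scores between groups with a two-sided Welch t-test computed from
closed-form moments (vectorised over thousands of genes; checked
against `t.test()` to 1e-12), and reports the signed log p,
SLP = sign(mean cases - mean controls) x (-log10 p), so a positive
SLP means cases carry more weighted burden. `rank_by_slp()` orders
genes by SLP and extracts the strict SLP > 2 and SLP < -2 lists.
Covariate handling (e.g. ancestry principal components) is reduced to
an optional pre-adjustment of scores by the caller; computing the
components themselves is out of scope.

## Expression module

The expression workflow mirrors how public inner-ear cell-type panels
are summarised:

1. `normalize_to_reference()` divides every value by the dataset's
   housekeeping reference level (*Hprt* by default). The reference
   level is taken as the mean of the reference gene's row across cell
   types — a per-dataset scalar, so relative cell-type contrasts within
   a dataset are preserved. Datasets where the reference is absent or
   zero are excluded, not errors.
2. `collapse_max()` takes, per gene and cell type, the maximum
   normalised level across datasets, ignoring stage. With an orthology
   table, genes without a one-to-one mapping are dropped first.
3. `scale_levels()` maps x < 1 to itself and x >= 1 to 1 + log10(x), a
   continuous monotone transform that sends 1-10 to 1-2 and 10-100 to
   2-3. Values above 100 keep growing as 1 + log10(x) rather than
   clamping at 3: the transform stays invertible and the panels this
   design anticipates top out around 70 anyway.
4. `variance_filter()` keeps genes whose variance across cell types
   strictly exceeds 0.15. Population variance (divisor n) is the
   default; the convention is configurable and recorded because the
   two differ exactly at small cell-type counts.
5. `cluster_genes()` is agglomerative hierarchical clustering
   (Euclidean distance, complete linkage by default) on genes and,
   separately, cell types. Rows are sorted by gene id before
   clustering, so the partition cannot depend on input order; the
   number of clusters k is supplied by the analyst, reflecting that
   dendrogram cutting is a judgment call, and `describe_clusters()`
   then automates the second, banding step: per cell-type group, mean
   scaled expression in (2, 3+] is high, (1, 2] middle, [0, 1] low.

## The synthetic data module

`sim_config()` fixes the study conditions for every generator. What the
defaults emulate, and why:

- **Cohort** (`simulate_cohort()`): 1000 participants, 1-3 visits with
  nondecreasing ages, ~97% with a visit at or beyond age 55, a latent
  hearing status driving consistent answer patterns at a 50/50 case
  fraction, and a 3% rate of exclusion-triggering answers spread over
  implants, otologic disorders, reversals, tinnitus and noise exposure
  so every phenotype rule is exercised.
- **Variants** (`simulate_variants()`): 2000 genes with lognormal
  lengths (sdlog 0.3) and Poisson variant counts proportional to
  length, mean 60 variants per gene; exome-weighted consequence
  classes; true allele frequencies from Beta(0.2, 4) truncated to
  (0, 0.5), the rare-skewed spectrum the frequency filters assume;
  deleteriousness scores drawn so that half the class-eligible variants
  clear the high-impact thresholds; external panel frequencies equal to
  the true frequency plus sampling noise; genotypes binomial(2, af),
  with the case-group probability multiplied by `spike_factor` (capped
  at 1) for high-impact variants of the spiked genes; DP/GQ drawn
  comfortably above the QC minima with low-quality calls injected at
  the 2% missing rate. The density — roughly 25 selected high-impact
  variants per gene at MAF < 0.1 — is about half the per-gene density
  that large exome cohorts report after equivalent filtering, and was
  chosen so that a 3-fold spike on 20 genes is reliably detectable by
  the 6xIQR rule at this cohort size; sparser panels leave short or
  low-frequency spiked genes under the detection threshold.
- **Gene lists** (`simulate_gene_lists()`): a "deafness" list built as
  spiked genes plus decoys and a disjoint "highly variable" list, both
  inside the universe, so enrichment has planted signal.
- **Expression** (`simulate_expression_panel()`): four datasets over a
  shared cochlear cell-type vocabulary, marker genes high in exactly
  one cell-type group (>10x), a constant *Hprt* row, and one dataset
  with reference level 0 to exercise the exclusion rule.

What the generator does *not* emulate: linkage disequilibrium,
population structure and relatedness, batch or platform effects,
correlated sequencing error, age- or sex-dependent allele effects, and
measured audiometry. Passing tests therefore demonstrate that the
statistics are implemented correctly and are calibrated under clean
binomial sampling — not that the pipeline is robust to confounding in
real cohort data, where ancestry adjustment and relatedness filtering
remain the analyst's responsibility.

## Numerical choices and degenerate inputs

- OLS residuals sum to zero to 1e-8 relative; slope/intercept match the
  normal-equation oracle to 1e-10.
- The hypergeometric tail and the exact HWE test are log-space sums,
  compared to enumeration at 1e-12.
- Quantiles default to type 7; tie-breaks in clustering are removed by
  sorting gene ids; cluster ids are relabelled in first-appearance
  order so partitions are comparable across runs.
- Degenerate inputs are first-class: all-identical control loads abort
  the regression with advice; D = 0 thresholds still apply strictly;
  zero-variance burden scores give p = 1 and SLP = 0; empty outlier
  lists yield empty (not missing) summaries; monomorphic sites have
  undefined excess heterozygosity and pass the HWE screen.
- All randomness is confined to the generators, which are pure
  functions of (config, seed); every analysis stage is deterministic.

## Problem sizes used in the packaged checks

The test suite runs most operations at 200-400 genes and 300-600
participants, and the calibration checks at the full study conditions
(2000 genes, 1000 participants): spiked-gene recovery and null-gene
contamination averaged over 10 seeds, burden type-I error over 2000
null gene-tests, and a planted-marker clustering recovered at adjusted
Rand index >= 0.9. `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed. These sizes are the package's
choice of a thorough-but-portable desk-scale experiment; the functions
themselves are vectorised over variants x samples matrices and scale
linearly in both.

## Known limitations

- The phenotype rules encode one defensible reading of longitudinal
  self-report; other readings (e.g. treating a reversal as difficulty
  evidence) change group sizes and are not toggleable beyond the
  documented options.
- The burden test assumes per-subject scores are approximately normal
  within groups; for very rare variants at small n the Welch test can
  be conservative.
- MSC mode restricts both the variant set and the gene universe to the
  cutoff table; comparisons between MSC and fixed-cutoff cells are
  therefore over different universes, as reflected in the recorded
  enrichment parameters.
- The expression module consumes per-cell-type summary matrices; it
  does not touch single-cell preprocessing, and its cluster
  descriptions inherit whatever cell-type grouping the analyst
  supplies.
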