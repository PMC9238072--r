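#' Quality-control and impact-classification configuration
#'
#' Thresholds for site and call quality control, and for predicted-impact
#' classification of annotated variants.
#'
#' @param min_qual Minimum site quality (QUAL), default 20, inclusive.
#' @param min_dp Minimum per-call read depth, default 10, inclusive.
#' @param min_gq Minimum per-call genotype quality, default 10, inclusive.
#' @param max_missing_fraction Maximum fraction of missing calls per site,
#'   default 0.10 (sites with strictly more are removed).
#' @param private_af_margin Margin added to the maximum external minor
#'   allele frequency when flagging privately common variants, default 0.4.
#' @param excess_het_max Maximum tolerated excess heterozygosity
#'   (O - E)/E, default 0.1; the filter also requires the exact
#'   Hardy-Weinberg test to reject at `hwe_alpha`.
#' @param hwe_alpha Significance level for the exact Hardy-Weinberg test,
#'   default 0.05.
#' @param cadd_cutoff CADD threshold for high impact (strict >), default
#'   25. Ignored for genes present in `msc_table` when one is supplied.
#' @param spliceai_cutoff SpliceAI delta-score threshold, default 0.5.
#' @param sutr_cutoff Sutr threshold for 5' UTR variants, default 1.
#' @param remm_cutoff ReMM threshold rescuing regulatory/other variants
#'   into the low-impact class, default 0.95.
#' @param msc_table Optional tibble with columns `gene_id` and
#'   `cadd_cutoff` giving gene-specific mutation significance cutoffs.
#'   Variants in genes absent from the table receive an `NA` impact and are
#'   dropped by [select_variants()], restricting the analysis to the genes
#'   with a defined cutoff.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(min_qual = 20, min_dp = 10, min_gq = 10,
                      max_missing_fraction = 0.10, private_af_margin = 0.4,
                      excess_het_max = 0.1, hwe_alpha = 0.05,
                      cadd_cutoff = 25, spliceai_cutoff = 0.5,
                      sutr_cutoff = 1, remm_cutoff = 0.95,
                      msc_table = NULL) {
  for (f in c("min_qual", "min_dp", "min_gq", "private_af_margin",
              "excess_het_max", "cadd_cutoff", "spliceai_cutoff",
              "sutr_cutoff", "remm_cutoff")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_config(f, "must be a single finite number")
    }
  }
  check_fraction(max_missing_fraction, "max_missing_fraction")
  check_fraction(hwe_alpha, "hwe_alpha")
  if (!is.null(msc_table) &&
      !all(c("gene_id", "cadd_cutoff") %in% names(msc_table))) {
    stop_config("msc_table", "needs columns gene_id and cadd_cutoff")
  }
  structure(list(min_qual = min_qual, min_dp = min_dp, min_gq = min_gq,
                 max_missing_fraction = max_missing_fraction,
                 private_af_margin = private_af_margin,
                 excess_het_max = excess_het_max, hwe_alpha = hwe_alpha,
                 cadd_cutoff = cadd_cutoff,
                 spliceai_cutoff = spliceai_cutoff,
                 sutr_cutoff = sutr_cutoff, remm_cutoff = remm_cutoff,
                 msc_table = msc_table),
            class = "qc_config")
}

#' Mask low-quality genotype calls
#'
#' Calls with read depth below `min_dp` or genotype quality below `min_gq`
#' become missing (`NA`); everything else is unchanged. These masked calls
#' count toward the per-site missingness filter in [site_qc()].
#'
#' @param geno List of variants x samples matrices `gt`, `dp`, `gq` (as
#'   produced by [simulate_variants()] or [read_variants_vcf()]).
#' @param config A [qc_config()].
#' @return The same list with `gt` masked.
#' @examples
#' geno <- list(gt = matrix(1L, 1, 1, dimnames = list("v1", "s1")),
#'              dp = matrix(9L, 1, 1), gq = matrix(30L, 1, 1))
#' mask_calls(geno, qc_config())$gt  # masked: DP below 10
#' @export
mask_calls <- function(geno, config = qc_config()) {
  check_geno_matrix(geno$gt)
  bad <- geno$dp < config$min_dp | geno$gq < config$min_gq
  gt <- geno$gt
  gt[bad] <- NA_integer_
  geno$gt <- gt
  geno
}

#' Excess heterozygosity and exact Hardy-Weinberg test
#'
#' Excess heterozygosity is (O - E)/E where O is the observed heterozygote
#' count and E = 2 p q N is the expected count under Hardy-Weinberg
#' proportions at the observed allele frequencies. The p value is from the
#' exact conditional test: the probability, given the allele counts, of a
#' heterozygote count at least as improbable as the observed one.
#'
#' @param n_ref_hom,n_het,n_alt_hom Genotype counts at one site.
#' @return A tibble with columns `excess` (`NA` when E = 0, i.e. the site
#'   is monomorphic) and `hwe_p`.
#' @examples
#' excess_heterozygosity(25, 50, 25)  # O = E at p = 0.5: excess 0
#' excess_heterozygosity(0, 100, 0)   # excess (100 - 50)/50 = 1
#' @export
excess_heterozygosity <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  if (any(n <= 0)) stop_validation("no genotyped calls at site")
  n_a <- 2 * n_ref_hom + n_het
  n_b <- 2 * n_alt_hom + n_het
  p_hat <- n_a / (2 * n)
  e <- 2 * p_hat * (1 - p_hat) * n
  excess <- ifelse(e > 0, (n_het - e) / e, NA_real_)
  hwe_p <- mapply(hwe_exact_p, n_ref_hom, n_het, n_alt_hom)
  tibble::tibble(excess = excess, hwe_p = hwe_p)
}

# exact conditional Hardy-Weinberg test: sum the probabilities of all
# heterozygote counts (given the allele counts) no more likely than the
# observed one
hwe_exact_p <- function(n_ref_hom, n_het, n_alt_hom) {
  n_a <- 2 * n_ref_hom + n_het
  n_b <- 2 * n_alt_hom + n_het
  m <- min(n_a, n_b)
  if (m == 0L) return(1)
  h <- seq(m %% 2L, m, by = 2L)
  logp <- h * log(2) - lfactorial((n_a - h) / 2) - lfactorial(h) -
    lfactorial((n_b - h) / 2)
  logp <- logp - logsumexp(logp)
  obs <- logp[match(n_het, h)]
  sum(exp(logp[logp <= obs + 1e-9]))
}

#' Maximum external minor allele frequency
#'
#' Folds each reported population frequency to the minor allele
#' (`min(af, 1 - af)`) and returns the maximum across populations. A
#' variant with no reported frequency is treated as novel (MAF 0).
#'
#' @param external_afs Named numeric vector of per-population allele
#'   frequencies; `NA` entries are ignored.
#' @return A single frequency in \[0, 0.5\].
#' @examples
#' max_external_maf(c(gnomad_nfe = 0.02, kg_eur = 0.05, topmed = 0.01))
#' max_external_maf(c(pop = 0.9))  # folded to 0.1
#' max_external_maf(numeric(0))    # novel: 0
#' @export
max_external_maf <- function(external_afs) {
  afs <- external_afs[!is.na(external_afs)]
  if (length(afs) == 0L) return(0)
  if (any(afs < 0 | afs > 1)) {
    stop_validation("allele frequencies must lie in [0, 1]")
  }
  max(pmin(afs, 1 - afs))
}

#' Add the maximum external MAF column to a variant table
#'
#' Applies [max_external_maf()] rowwise over every `af_*` column.
#'
#' @param variants Annotated variant tibble with zero or more `af_*`
#'   columns of per-population allele frequencies.
#' @return `variants` with a `max_external_maf` column appended.
#' @export
add_max_external_maf <- function(variants) {
  af_cols <- grep("^af_", names(variants), value = TRUE)
  if (length(af_cols) == 0L) {
    return(dplyr::mutate(variants, max_external_maf = 0))
  }
  af <- as.matrix(variants[af_cols])
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stop_validation("allele frequencies must lie in [0, 1]")
  }
  folded <- pmin(af, 1 - af)
  mx <- apply(folded, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) max(x) else 0
  })
  dplyr::mutate(variants, max_external_maf = mx)
}

#' Site-level quality control
#'
#' Applies the site filters in order: site quality (QUAL below `min_qual`),
#' missingness (strictly more than `max_missing_fraction` of calls
#' missing), private allele frequency (cohort alternate-allele frequency
#' exceeding the maximum external MAF plus `private_af_margin`), and excess
#' heterozygosity (exact Hardy-Weinberg test rejecting at `hwe_alpha`
#' together with excess heterozygosity above `excess_het_max`). The
#' recorded reason is the first failing rule.
#'
#' Genotypes should already be masked by [mask_calls()] so that
#' low-quality calls count as missing.
#'
#' @param variants Annotated variant tibble (needs `variant_id`, `qual`
#'   and `af_*` columns).
#' @param geno Masked genotype list (only `gt` is used).
#' @param config A [qc_config()].
#' @return A tibble with one row per variant: `variant_id`, `pass`,
#'   `reason` (`NA` when passing), `missing_fraction`, `cohort_af`,
#'   `max_external_maf`, `excess_het`, `hwe_p`.
#' @export
site_qc <- function(variants, geno, config = qc_config()) {
  gt <- check_geno_matrix(geno$gt)
  if (ncol(gt) == 0L) stop_validation("no genotype calls supplied")
  gt <- gt[variants$variant_id, , drop = FALSE]

  n_samples <- ncol(gt)
  n_missing <- rowSums(is.na(gt))
  n_called <- n_samples - n_missing
  missing_fraction <- n_missing / n_samples
  alt_alleles <- rowSums(gt, na.rm = TRUE)
  cohort_af <- ifelse(n_called > 0, alt_alleles / (2 * n_called), NA_real_)

  if (!"max_external_maf" %in% names(variants)) {
    variants <- add_max_external_maf(variants)
  }
  max_maf <- variants$max_external_maf

  n_het <- rowSums(gt == 1L, na.rm = TRUE)
  n_alt_hom <- rowSums(gt == 2L, na.rm = TRUE)
  n_ref_hom <- n_called - n_het - n_alt_hom
  p_hat <- ifelse(n_called > 0,
                  (2 * n_ref_hom + n_het) / (2 * n_called), NA_real_)
  e_het <- 2 * p_hat * (1 - p_hat) * n_called
  excess <- ifelse(!is.na(e_het) & e_het > 0,
                   (n_het - e_het) / e_het, NA_real_)

  # the exact test is only consulted where the excess rule can fire
  need_hwe <- !is.na(excess) & excess > config$excess_het_max
  hwe_p <- rep(NA_real_, nrow(variants))
  hwe_p[need_hwe] <- mapply(hwe_exact_p, n_ref_hom[need_hwe],
                            n_het[need_hwe], n_alt_hom[need_hwe])

  undefined <- n_called == 0L
  reason <- dplyr::case_when(
    variants$qual < config$min_qual ~ "qual",
    missing_fraction > config$max_missing_fraction ~ "missingness",
    undefined ~ "all_missing",
    cohort_af > max_maf + config$private_af_margin ~ "private_af",
    need_hwe & hwe_p < config$hwe_alpha ~ "excess_het",
    TRUE ~ NA_character_)

  tibble::tibble(variant_id = variants$variant_id,
                 pass = unname(is.na(reason)), reason = unname(reason),
                 missing_fraction = unname(missing_fraction),
                 cohort_af = unname(cohort_af),
                 max_external_maf = unname(max_maf),
                 excess_het = unname(excess), hwe_p = unname(hwe_p))
}

#' Classify predicted variant impact
#'
#' Two inclusive impact levels are defined. High impact: variants in coding
#' regions, splice sites or mature miRNAs with CADD strictly above the
#' cutoff (gene-specific when an MSC table is configured) or SpliceAI
#' strictly above its cutoff, and 5' UTR variants with Sutr strictly above
#' its cutoff. Low impact: every high-impact variant, all coding, splice,
#' miRNA, 5' UTR and 3' UTR variants, and variants of any other class whose
#' ReMM score is strictly above its cutoff. Everything else is `none`.
#'
#' @param variants Annotated variant tibble with columns `gene_id`,
#'   `consequence`, `cadd`, `spliceai`, `sutr`, `remm` (score columns may
#'   contain `NA` for absent scores).
#' @param config A [qc_config()]; when `config$msc_table` is set, variants
#'   in genes without a cutoff get `NA` impact.
#' @return `variants` with an `impact` column (`"high"`, `"low"`,
#'   `"none"`, or `NA` under MSC mode for unscored genes).
#' @export
classify_impact <- function(variants, config = qc_config()) {
  cons <- most_severe_consequence(variants$consequence)
  category <- consequence_category(cons)

  if (is.null(config$msc_table)) {
    cadd_cut <- rep(config$cadd_cutoff, nrow(variants))
    unscored_gene <- rep(FALSE, nrow(variants))
  } else {
    idx <- match(variants$gene_id, config$msc_table$gene_id)
    cadd_cut <- config$msc_table$cadd_cutoff[idx]
    unscored_gene <- is.na(idx)
  }

  cadd <- dplyr::coalesce(variants$cadd, -Inf)
  spliceai <- dplyr::coalesce(variants$spliceai, -Inf)
  sutr <- dplyr::coalesce(variants$sutr, -Inf)
  remm <- dplyr::coalesce(variants$remm, -Inf)

  high <- (category %in% c("coding", "splice", "miRNA") &
             (cadd > cadd_cut | spliceai > config$spliceai_cutoff)) |
    (category == "utr5" & sutr > config$sutr_cutoff)
  low <- high |
    category %in% c("coding", "splice", "miRNA", "utr5", "utr3") |
    (category == "other" & remm > config$remm_cutoff)

  impact <- dplyr::case_when(high ~ "high", low ~ "low", TRUE ~ "none")
  impact[unscored_gene] <- NA_character_
  dplyr::mutate(variants, impact = impact)
}

#' Select variants by impact and allele frequency
#'
#' Keeps QC-passing variants whose maximum external minor allele frequency
#' is strictly below `maf_cutoff` and whose impact is at least the
#' requested level (the low-impact class includes the high-impact class).
#' With a gene restriction (MSC mode), variants in other genes are
#' dropped, as are variants with `NA` impact.
#'
#' @param variants Variant tibble with an `impact` column (see
#'   [classify_impact()]); `max_external_maf` is added if absent.
#' @param impact `"high"` or `"low"`.
#' @param maf_cutoff Frequency cutoff in (0, 1].
#' @param qc Optional [site_qc()] result; failing variants are dropped.
#' @param gene_restriction Optional character vector of gene ids to
#'   restrict to.
#' @return The filtered variant tibble.
#' @export
select_variants <- function(variants, impact = c("high", "low"),
                            maf_cutoff = 0.1, qc = NULL,
                            gene_restriction = NULL) {
  impact <- match.arg(impact)
  if (!is.numeric(maf_cutoff) || length(maf_cutoff) != 1L ||
      maf_cutoff <= 0 || maf_cutoff > 1) {
    stop_validation("maf_cutoff must lie in (0, 1]")
  }
  if (!"impact" %in% names(variants)) {
    stop_validation("variants need an `impact` column; run classify_impact()")
  }
  if (!"max_external_maf" %in% names(variants)) {
    variants <- add_max_external_maf(variants)
  }
  if (!is.null(qc)) {
    keep_ids <- qc$variant_id[qc$pass]
    variants <- dplyr::filter(variants, .data$variant_id %in% keep_ids)
  }
  wanted <- if (impact == "high") "high" else c("high", "low")
  out <- variants |>
    dplyr::filter(!is.na(.data$impact), .data$impact %in% wanted,
                  .data$max_external_maf < maf_cutoff)
  if (!is.null(gene_restriction)) {
    out <- dplyr::filter(out, .data$gene_id %in% gene_restriction)
  }
  out
}
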