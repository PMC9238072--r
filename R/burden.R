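#' Weighted burden test configuration
#'
#' @param weight_max Maximum variant weight W (assigned to a variant with
#'   MAF 0); default 10.
#' @param maf_cap The analysis MAF cutoff; a variant at the cap receives
#'   weight 1. Must lie in (0, 0.5]; default 0.1.
#' @return An object of class `burden_config`.
#' @export
burden_config <- function(weight_max = 10, maf_cap = 0.1) {
  if (!is.numeric(weight_max) || length(weight_max) != 1L ||
      weight_max < 1) {
    stop_config("weight_max", "must be a single number >= 1")
  }
  if (!is.numeric(maf_cap) || length(maf_cap) != 1L || maf_cap <= 0 ||
      maf_cap > 0.5) {
    stop_config("maf_cap", "must lie in (0, 0.5]")
  }
  structure(list(weight_max = weight_max, maf_cap = maf_cap),
            class = "burden_config")
}

#' Minor-allele-frequency variant weight
#'
#' Linear ramp from `weight_max` at MAF 0 down to 1 at the MAF cap, so
#' rarer variants are weighted more heavily:
#' w = 1 + (W - 1) (cap - maf) / cap.
#'
#' @param maf Minor allele frequency (or vector), each in \[0, maf_cap\].
#' @param config A [burden_config()].
#' @return Numeric weights, strictly decreasing in `maf`.
#' @examples
#' variant_weight(c(0, 0.05, 0.1), burden_config())  # 10, 5.5, 1
#' @export
variant_weight <- function(maf, config = burden_config()) {
  if (any(!is.finite(maf)) || any(maf < 0)) {
    stop_validation("maf must be finite and nonnegative")
  }
  if (any(maf > config$maf_cap)) {
    stop_validation("maf exceeds the configured maf_cap")
  }
  1 + (config$weight_max - 1) * (config$maf_cap - maf) / config$maf_cap
}

#' Per-subject, per-gene burden scores
#'
#' Each subject's score for a gene is the weighted sum of their alternate
#' allele counts over the gene's variants; missing genotypes contribute 0.
#'
#' @param variants Filtered variant tibble with `variant_id`, `gene_id`
#'   and `max_external_maf` columns (the weighting frequency).
#' @param geno Genotype list (masked); `gt` rows must cover the variants.
#' @param config A [burden_config()].
#' @return A genes x subjects numeric matrix of scores.
#' @export
subject_gene_scores <- function(variants, geno,
                                config = burden_config()) {
  gt <- check_geno_matrix(geno$gt)
  if (nrow(variants) == 0L) {
    stop_validation("no variants to score")
  }
  if (!"max_external_maf" %in% names(variants)) {
    variants <- add_max_external_maf(variants)
  }
  w <- variant_weight(pmin(variants$max_external_maf, config$maf_cap),
                      config)
  g <- gt[variants$variant_id, , drop = FALSE]
  g[is.na(g)] <- 0L
  rowsum(g * w, group = variants$gene_id)
}

#' Weighted burden test for one gene or many
#'
#' Compares mean per-subject scores between the hearing difficulty (case)
#' and normal hearing (control) groups with a two-sided Welch t-test and
#' reports the signed log p value: SLP = sign(mean cases - mean controls)
#' x (-log10 p). A gene whose scores are constant and equal in both groups
#' gets p = 1, SLP = 0.
#'
#' @param scores A genes x subjects score matrix from
#'   [subject_gene_scores()] (or a single named numeric vector of
#'   per-subject scores).
#' @param calls Phenotype calls from [classify_hearing()].
#' @return A tibble with one row per gene: `gene_id`, `mean_case`,
#'   `mean_control`, `statistic`, `df`, `p`, `slp`.
#' @export
burden_test <- function(scores, calls) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1L,
                     dimnames = list("gene", names(scores)))
  }
  cases <- intersect(colnames(scores),
                     calls$participant_id[calls$group == "difficulty"])
  controls <- intersect(colnames(scores),
                        calls$participant_id[calls$group == "normal"])
  if (length(cases) < 2L || length(controls) < 2L) {
    stop_validation("need at least 2 scored subjects per phenotype group")
  }
  sc <- scores[, cases, drop = FALSE]
  sn <- scores[, controls, drop = FALSE]
  n1 <- length(cases)
  n2 <- length(controls)
  m1 <- rowMeans(sc)
  m2 <- rowMeans(sn)
  v1 <- rowSums((sc - m1)^2) / (n1 - 1)
  v2 <- rowSums((sn - m2)^2) / (n2 - 1)

  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  p <- ifelse(is.na(stat), 1, 2 * pt(abs(stat), df, lower.tail = FALSE))
  # degenerate case: both groups constant; equal means get p = 1 above,
  # unequal constant means cannot occur with se2 = 0 unless means differ
  p[!is.na(stat) & se2 == 0] <- 1
  slp <- sign(m1 - m2) * (-log10(p))
  slp[p == 1 | m1 == m2] <- 0

  tibble::tibble(gene_id = rownames(scores), mean_case = unname(m1),
                 mean_control = unname(m2), statistic = unname(stat),
                 df = unname(df), p = unname(p), slp = unname(slp))
}

#' Rank burden results by signed log p
#'
#' Orders genes by descending SLP and extracts the two extreme lists:
#' genes with SLP strictly above `threshold` (more variants in cases) and
#' strictly below `-threshold` (more variants in controls).
#'
#' @param results A burden result tibble from [burden_test()].
#' @param threshold SLP threshold (default 2, i.e. p < 0.01 one-signed).
#' @return A list with `ranked` (the tibble with a `rank` column,
#'   descending SLP), `slp_positive` and `slp_negative` (character vectors
#'   of gene ids).
#' @export
rank_by_slp <- function(results, threshold = 2) {
  ranked <- results |>
    dplyr::arrange(dplyr::desc(.data$slp), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  list(ranked = ranked,
       slp_positive = ranked$gene_id[ranked$slp > threshold],
       slp_negative = ranked$gene_id[ranked$slp < -threshold])
}
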