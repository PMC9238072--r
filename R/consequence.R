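#' Variant consequence vocabulary
#'
#' The ordered consequence vocabulary used throughout the package, from most
#' to least severe. Each consequence term belongs to a region category that
#' drives impact classification: `coding` (including essential splice-site
#' changes handled separately), `splice`, `miRNA`, `utr5`, `utr3` and
#' `other` (regulatory, intronic, intergenic).
#'
#' @return A tibble with columns `consequence` (term), `severity_rank`
#'   (1 = most severe) and `category`.
#' @examples
#' consequence_vocabulary()
#' @export
consequence_vocabulary <- function() {
  .consequence_vocab
}

# built once at load: the vocabulary is consulted per variant
.consequence_vocab <- local({
  tibble::tribble(
    ~consequence,               ~category,
    "stop_gained",              "coding",
    "stop_lost",                "coding",
    "start_lost",               "coding",
    "frameshift_variant",       "coding",
    "splice_site_variant",      "splice",
    "inframe_insertion",        "coding",
    "inframe_deletion",         "coding",
    "missense_variant",         "coding",
    "mature_miRNA_variant",     "miRNA",
    "5_prime_UTR_variant",      "utr5",
    "3_prime_UTR_variant",      "utr3",
    "synonymous_variant",       "coding",
    "regulatory_region_variant","other",
    "intron_variant",           "other",
    "intergenic_variant",       "other"
  ) |>
    dplyr::mutate(severity_rank = dplyr::row_number(), .after = 1L)
})

consequence_rank <- function(consequence) {
  vocab <- consequence_vocabulary()
  idx <- match(consequence, vocab$consequence)
  if (anyNA(idx)) {
    stop_validation(sprintf(
      "unknown consequence class: %s",
      paste(unique(consequence[is.na(idx)]), collapse = ", ")))
  }
  vocab$severity_rank[idx]
}

consequence_category <- function(consequence) {
  vocab <- consequence_vocabulary()
  idx <- match(consequence, vocab$consequence)
  if (anyNA(idx)) {
    stop_validation(sprintf(
      "unknown consequence class: %s",
      paste(unique(consequence[is.na(idx)]), collapse = ", ")))
  }
  vocab$category[idx]
}

# a variant may carry several "&"- or ","-separated consequence terms;
# the most severe one is used (the most deleterious consequence per variant)
most_severe_consequence <- function(consequence) {
  out <- consequence
  multi <- grepl("[&,]", consequence)
  if (any(multi)) {
    out[multi] <- vapply(strsplit(consequence[multi], "[&,]"),
                         function(terms) {
                           terms <- trimws(terms)
                           terms[which.min(consequence_rank(terms))]
                         }, character(1))
  }
  consequence_rank(out)  # validates every term
  out
}
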