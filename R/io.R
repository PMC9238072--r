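#' Read and write cohort, gene-list and expression tables
#'
#' Plain-text interchange for every input the pipeline consumes: cohorts as
#' one-row-per-visit TSV, gene lists as one-gene-per-line text, expression
#' datasets as gene x cell-type TSV, and annotated variants with genotypes
#' as VCF (see [write_variants_vcf()]).
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort_tsv()` returns a cohort tibble; writers return the
#'   path invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' @rdname cohort_io
#' @param genes Character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_gene_list <- function(path) {
  genes <- readLines(path)
  genes[nzchar(trimws(genes))]
}

#' @rdname cohort_io
#' @param dataset An [expression_dataset()].
#' @export
write_expression_tsv <- function(dataset, path) {
  df <- data.frame(gene_id = rownames(dataset$mat), dataset$mat,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @param dataset_id,stage,reference_gene Metadata for the dataset read
#'   from `path`.
#' @export
read_expression_tsv <- function(path, dataset_id, stage,
                                reference_gene = "Hprt") {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  expression_dataset(dataset_id, stage, mat, reference_gene)
}

#' Write annotated variants and genotypes as VCF
#'
#' Emits a plain-text VCF 4.2 file with the annotation scores as INFO keys
#' (GENE, CSQ, CADD, SPLICEAI, SUTR, REMM and one AF_* key per external
#' population) and per-sample GT:DP:GQ genotype fields.
#'
#' @param variants Annotated variant tibble.
#' @param geno Genotype list (`gt`, `dp`, `gq`), samples as columns.
#' @param path Output path (plain text, not compressed).
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(variants, geno, path) {
  gt <- check_geno_matrix(geno$gt)
  samples <- colnames(gt)
  af_cols <- grep("^af_", names(variants), value = TRUE)

  info_defs <- c(
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD score">',
    '##INFO=<ID=SPLICEAI,Number=1,Type=Float,Description="SpliceAI delta score">',
    '##INFO=<ID=SUTR,Number=1,Type=Float,Description="Sutr 5p UTR score">',
    '##INFO=<ID=REMM,Number=1,Type=Float,Description="ReMM score">',
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="External allele frequency (%s)">',
            toupper(af_cols), sub("^af_", "", af_cols)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hearload",
    info_defs,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))

  fmt_num <- function(x) ifelse(is.na(x), NA, format(x, digits = 6,
                                                     trim = TRUE,
                                                     scientific = FALSE))
  info_fields <- list(GENE = variants$gene_id, CSQ = variants$consequence,
                      CADD = fmt_num(variants$cadd),
                      SPLICEAI = fmt_num(variants$spliceai),
                      SUTR = fmt_num(variants$sutr),
                      REMM = fmt_num(variants$remm))
  for (a in af_cols) info_fields[[toupper(a)]] <- fmt_num(variants[[a]])
  info <- vapply(seq_len(nrow(variants)), function(i) {
    kv <- purrr::imap_chr(info_fields, function(v, k) {
      if (is.na(v[i])) NA_character_ else paste0(k, "=", v[i])
    })
    paste(kv[!is.na(kv)], collapse = ";")
  }, character(1))

  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno$gt[variants$variant_id, ,
                                                  drop = FALSE] + 1L],
                   nrow = nrow(variants))
  gt_str[is.na(gt_str)] <- "./."
  dp <- geno$dp[variants$variant_id, , drop = FALSE]
  gq <- geno$gq[variants$variant_id, , drop = FALSE]
  calls <- matrix(paste(gt_str, dp, gq, sep = ":"), nrow = nrow(variants))

  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt,
                fmt_num(variants$qual), "PASS", info, "GT:DP:GQ",
                apply(calls, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read annotated variants and genotypes from VCF
#'
#' Parses a VCF written by [write_variants_vcf()] (or any biallelic VCF
#' carrying the same INFO keys and GT:DP:GQ genotypes) into the variant
#' tibble and genotype matrices the rest of the package consumes.
#'
#' @param path VCF file path.
#' @return A list with `variants` and `geno` (`gt`, `dp`, `gq`).
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_validation("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  info_chr <- function(key) vcfR::extract.info(v, element = key)

  info_keys <- unique(unlist(regmatches(
    v@fix[, "INFO"], gregexpr("(?<=^|;)[A-Za-z0-9_]+(?==)",
                              v@fix[, "INFO"], perl = TRUE))))
  af_keys <- grep("^AF_", info_keys, value = TRUE)

  variants <- tibble::tibble(
    variant_id = fix$ID,
    gene_id = info_chr("GENE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    consequence = info_chr("CSQ"),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    cadd = info_num("CADD"), spliceai = info_num("SPLICEAI"),
    sutr = info_num("SUTR"), remm = info_num("REMM"))
  for (k in af_keys) variants[[tolower(k)]] <- info_num(k)

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(NA_integer_, nrow = nrow(gt_raw), ncol = ncol(gt_raw),
               dimnames = list(variants$variant_id, colnames(gt_raw)))
  gt[gt_raw %in% c("0/0", "0|0")] <- 0L
  gt[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_raw %in% c("1/1", "1|1")] <- 2L
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  dimnames(dp) <- dimnames(gq) <- dimnames(gt)

  list(variants = variants, geno = list(gt = gt, dp = dp, gq = gq))
}

#' Write regression fit parameters as JSON
#'
#' @param fit A `load_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_validation("writing JSON requires the jsonlite package")
  }
  jsonlite::write_json(list(slope = fit$slope, intercept = fit$intercept,
                            n = fit$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
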