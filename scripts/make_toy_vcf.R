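# Builds the packaged toy VCF fixture and its hand-annotated expected
# decision table. Every expectation below is written down from the filter
# definitions by construction, never computed by running the pipeline.
suppressMessages(library(hearload))
suppressMessages(library(tibble))

samples <- sprintf("s%02d", 1:10)
n <- length(samples)

# row helper: default annotation is a clean passing missense variant
row <- function(id, consequence = "missense_variant", qual = 100,
                cadd = NA, spliceai = NA, sutr = NA, remm = NA,
                af_gnomad_nfe = NA, af_kg_eur = NA) {
  tibble(variant_id = id, gene_id = paste0("G_", id), chrom = "chr1",
         pos = 0L, ref = "A", alt = "G", consequence = consequence,
         qual = qual, cadd = cadd, spliceai = spliceai, sutr = sutr,
         remm = remm, af_gnomad_nfe = af_gnomad_nfe, af_kg_eur = af_kg_eur)
}

variants <- dplyr::bind_rows(
  row("v01", cadd = 30, af_gnomad_nfe = 0.01),
  row("v02", cadd = 30, af_gnomad_nfe = 0.01, qual = 19),
  row("v03", cadd = 30, af_gnomad_nfe = 0.01, qual = 20),
  row("v04", cadd = 30, af_gnomad_nfe = 0.01),  # 2/10 calls DP-masked
  row("v05", cadd = 30, af_gnomad_nfe = 0.01),  # 1/10 calls DP-masked
  row("v06", cadd = 30, af_gnomad_nfe = 0.02),  # all het, private
  row("v07", cadd = 30, af_gnomad_nfe = 0.45),  # all het, excess het
  row("v08", cadd = 30, af_gnomad_nfe = 0.45),  # 3 het of 10, HWE holds
  row("v09", consequence = "5_prime_UTR_variant", sutr = 1.5,
      af_gnomad_nfe = 0.01),
  row("v10", consequence = "5_prime_UTR_variant", sutr = 1.0,
      af_gnomad_nfe = 0.01),
  row("v11", consequence = "5_prime_UTR_variant", sutr = 0.5,
      af_gnomad_nfe = 0.01),
  row("v12", consequence = "3_prime_UTR_variant", cadd = 40,
      af_gnomad_nfe = 0.01),
  row("v13", consequence = "regulatory_region_variant", remm = 0.96,
      af_gnomad_nfe = 0.01),
  row("v14", consequence = "regulatory_region_variant", remm = 0.95,
      af_gnomad_nfe = 0.01),
  row("v15", consequence = "intron_variant", remm = 0.2,
      af_gnomad_nfe = 0.01),
  row("v16", consequence = "splice_site_variant", cadd = 5,
      spliceai = 0.6, af_gnomad_nfe = 0.01),
  row("v17", consequence = "splice_site_variant", cadd = 5,
      spliceai = 0.5, af_gnomad_nfe = 0.01),
  row("v18", cadd = 25, af_gnomad_nfe = 0.01),
  row("v19", consequence = "mature_miRNA_variant", cadd = 26,
      af_gnomad_nfe = 0.01),
  row("v20", consequence = "synonymous_variant", cadd = 2,
      af_gnomad_nfe = 0.01),
  row("v21", cadd = 30, af_gnomad_nfe = 0.15),
  row("v22", cadd = 30, af_gnomad_nfe = 0.95, af_kg_eur = 0.01),
  row("v23", cadd = 30),                         # novel: no external AF
  row("v24", consequence = "stop_gained", cadd = 35,
      af_gnomad_nfe = 0.004),
  row("v25", consequence = "frameshift_variant", cadd = 28,
      af_gnomad_nfe = 0.004),
  row("v26", consequence = "missense_variant&splice_site_variant",
      spliceai = 0.7, af_gnomad_nfe = 0.01),
  row("v27", cadd = 30, af_gnomad_nfe = 0.01),  # 3/10 calls GQ-masked
  row("v28", cadd = 10, af_gnomad_nfe = 0.01),
  row("v29", consequence = "stop_lost", cadd = 30, af_gnomad_nfe = 0.3),
  row("v30", consequence = "inframe_deletion", cadd = 26,
      af_gnomad_nfe = 0.01))
variants$pos <- seq_len(nrow(variants)) * 500L + 10000L

nv <- nrow(variants)
gt <- matrix(0L, nv, n, dimnames = list(variants$variant_id, samples))
gt[, c("s01", "s02")] <- 1L          # default: two heterozygotes
gt["v06", ] <- 1L                    # every call heterozygous
gt["v07", ] <- 1L
gt["v08", ] <- 0L; gt["v08", c("s01", "s02", "s03")] <- 1L
dp <- matrix(30L, nv, n, dimnames = dimnames(gt))
gq <- matrix(90L, nv, n, dimnames = dimnames(gt))
dp["v04", c("s01", "s02")] <- 5L
dp["v05", "s01"] <- 5L
gq["v27", c("s01", "s02", "s03")] <- 5L

write_variants_vcf(variants, list(gt = gt, dp = dp, gq = gq),
                   "inst/extdata/toy_variants.vcf")

# hand-annotated expectations under the default QC configuration:
# pass/reason from the site rules, impact from the two-tier rules, and
# the folded maximum external MAF
expected <- tribble(
  ~variant_id, ~pass, ~reason,       ~impact, ~max_external_maf,
  "v01", TRUE,  NA,                  "high",  0.01,
  "v02", FALSE, "qual",              "high",  0.01,
  "v03", TRUE,  NA,                  "high",  0.01,
  "v04", FALSE, "missingness",       "high",  0.01,
  "v05", TRUE,  NA,                  "high",  0.01,
  "v06", FALSE, "private_af",        "high",  0.02,
  "v07", FALSE, "excess_het",        "high",  0.45,
  "v08", TRUE,  NA,                  "high",  0.45,
  "v09", TRUE,  NA,                  "high",  0.01,
  "v10", TRUE,  NA,                  "low",   0.01,
  "v11", TRUE,  NA,                  "low",   0.01,
  "v12", TRUE,  NA,                  "low",   0.01,
  "v13", TRUE,  NA,                  "low",   0.01,
  "v14", TRUE,  NA,                  "none",  0.01,
  "v15", TRUE,  NA,                  "none",  0.01,
  "v16", TRUE,  NA,                  "high",  0.01,
  "v17", TRUE,  NA,                  "low",   0.01,
  "v18", TRUE,  NA,                  "low",   0.01,
  "v19", TRUE,  NA,                  "high",  0.01,
  "v20", TRUE,  NA,                  "low",   0.01,
  "v21", TRUE,  NA,                  "high",  0.15,
  "v22", TRUE,  NA,                  "high",  0.05,
  "v23", TRUE,  NA,                  "high",  0,
  "v24", TRUE,  NA,                  "high",  0.004,
  "v25", TRUE,  NA,                  "high",  0.004,
  "v26", TRUE,  NA,                  "high",  0.01,
  "v27", FALSE, "missingness",       "high",  0.01,
  "v28", TRUE,  NA,                  "low",   0.01,
  "v29", TRUE,  NA,                  "high",  0.3,
  "v30", TRUE,  NA,                  "high",  0.01)
write.table(expected, "inst/extdata/toy_variants_expected.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(variants), "variants\n")
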