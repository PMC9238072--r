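test_that("call masking applies the DP/GQ minima inclusively", {
  gt <- matrix(c(1L, 1L, 2L, 0L), 2, 2,
               dimnames = list(c("v1", "v2"), c("s1", "s2")))
  dp <- matrix(c(9L, 10L, 30L, 30L), 2, 2)
  gq <- matrix(c(30L, 10L, 9L, 99L), 2, 2)
  masked <- mask_calls(make_geno(gt, dp, gq))$gt
  expect_true(is.na(masked["v1", "s1"]))   # DP 9 below the minimum
  expect_equal(masked["v2", "s1"], 1L)     # DP 10, GQ 10: kept
  expect_true(is.na(masked["v1", "s2"]))   # GQ 9 below the minimum
  expect_equal(masked["v2", "s2"], 0L)

  # all calls passing: identity
  clean <- make_geno(gt)
  expect_identical(mask_calls(clean)$gt, gt)
})

test_that("excess heterozygosity follows (O - E)/E", {
  r <- excess_heterozygosity(25, 50, 25)
  expect_equal(r$excess, 0)
  r <- excess_heterozygosity(0, 100, 0)
  expect_equal(r$excess, 1.0)
  # monomorphic site: E = 0, excess undefined
  r <- excess_heterozygosity(50, 0, 0)
  expect_true(is.na(r$excess))
  expect_equal(r$hwe_p, 1)
  expect_error(excess_heterozygosity(0, 0, 0),
               class = "hearload_validation_error")
})

test_that("exact HWE test agrees with full enumeration", {
  cases <- list(c(30, 30, 40), c(25, 50, 25), c(0, 10, 0), c(7, 3, 0),
                c(1, 1, 1), c(10, 5, 10), c(18, 2, 5), c(0, 2, 23))
  for (cs in cases) {
    got <- excess_heterozygosity(cs[1], cs[2], cs[3])$hwe_p
    expect_equal(got, hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12,
                 info = paste(cs, collapse = "/"))
  }
})

test_that("site QC fails variants on the first violated rule in order", {
  n <- 100
  samples <- sprintf("s%03d", seq_len(n))
  base_gt <- matrix(0L, 1, n, dimnames = list("v01", samples))
  base_gt[1, 1:10] <- 1L
  v <- make_variants(1, af_pop1 = 0.05)

  # QUAL below 20 fails, 20 itself passes
  qc <- site_qc(dplyr::mutate(v, qual = 19), make_geno(base_gt))
  expect_false(qc$pass)
  expect_equal(qc$reason, "qual")
  qc <- site_qc(dplyr::mutate(v, qual = 20), make_geno(base_gt))
  expect_true(qc$pass)

  # 11 of 100 missing fails, 10 of 100 passes
  gt <- base_gt; gt[1, 90:100] <- NA_integer_
  expect_equal(site_qc(v, make_geno(gt))$reason, "missingness")
  gt <- base_gt; gt[1, 91:100] <- NA_integer_
  expect_true(site_qc(v, make_geno(gt))$pass)

  # cohort AF 0.45 against max external MAF 0.02: 0.45 > 0.42
  gt <- matrix(0L, 1, n, dimnames = list("v01", samples))
  gt[1, 1:45] <- 2L
  qc <- site_qc(make_variants(1, af_pop1 = 0.02), make_geno(gt))
  expect_equal(qc$reason, "private_af")

  # same cohort AF but external MAF 0.1 gives margin 0.5: passes the
  # private rule, and balanced hom/het keeps heterozygosity in check
  gt <- matrix(c(rep(2L, 20), rep(1L, 50), rep(0L, 30)), 1, n,
               dimnames = list("v01", samples))
  qc <- site_qc(make_variants(1, af_pop1 = 0.45), make_geno(gt))
  expect_true(qc$pass)

  # 10 samples all heterozygous: excess 1.0 and exact test rejects
  gt <- matrix(1L, 1, 10, dimnames = list("v01", samples[1:10]))
  qc <- site_qc(make_variants(1, af_pop1 = 0.45), make_geno(gt))
  expect_equal(qc$reason, "excess_het")
  expect_equal(qc$excess_het, 1.0)
  expect_lt(hwe_oracle(0, 10, 0), 0.05)
  expect_equal(qc$hwe_p, hwe_oracle(0, 10, 0), tolerance = 1e-12)

  # empty genotype list is a validation error
  expect_error(site_qc(v, make_geno(base_gt[, 0, drop = FALSE])),
               class = "hearload_validation_error")
})

test_that("site QC decisions are order-independent in the samples", {
  withr::local_seed(1)
  n <- 60
  gt <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), 20 * n, replace = TRUE),
               20, n, dimnames = list(sprintf("v%02d", 1:20),
                                      sprintf("s%03d", 1:n)))
  v <- make_variants(20, af_pop1 = 0.05)
  qc1 <- site_qc(v, make_geno(gt))
  perm <- sample(n)
  qc2 <- site_qc(v, make_geno(gt[, perm]))
  expect_equal(qc1$pass, qc2$pass)
  expect_equal(qc1$reason, qc2$reason)
})

test_that("maximum external MAF folds and defaults to novel", {
  expect_equal(max_external_maf(c(gnomad_nfe = 0.02, kg_eur = 0.05,
                                  topmed = 0.01)), 0.05)
  expect_equal(max_external_maf(numeric(0)), 0)
  expect_equal(max_external_maf(c(pop = 0.9)), 0.1)
  expect_equal(max_external_maf(c(a = NA, b = 0.2)), 0.2)
  expect_error(max_external_maf(c(pop = 1.2)),
               class = "hearload_validation_error")

  tab <- add_max_external_maf(tibble::tibble(
    variant_id = c("a", "b"), af_p1 = c(0.9, NA), af_p2 = c(0.02, NA)))
  expect_equal(tab$max_external_maf, c(0.1, 0))
})

test_that("impact classification follows the two-tier rules strictly", {
  classify1 <- function(...) classify_impact(make_variants(1, ...))$impact
  expect_equal(classify1(consequence = "missense_variant", cadd = 30),
               "high")
  expect_equal(classify1(consequence = "missense_variant", cadd = 25),
               "low")  # strict inequality at the cutoff
  expect_equal(classify1(consequence = "splice_site_variant", cadd = 10,
                         spliceai = 0.6), "high")
  expect_equal(classify1(consequence = "5_prime_UTR_variant", sutr = 1.5),
               "high")
  expect_equal(classify1(consequence = "5_prime_UTR_variant", sutr = 1),
               "low")
  expect_equal(classify1(consequence = "3_prime_UTR_variant", cadd = 40),
               "low")  # 3' UTR is unconditionally low impact
  expect_equal(classify1(consequence = "regulatory_region_variant",
                         remm = 0.96), "low")
  expect_equal(classify1(consequence = "regulatory_region_variant",
                         remm = 0.95), "none")
  expect_equal(classify1(consequence = "mature_miRNA_variant", cadd = 26),
               "high")
  expect_equal(classify1(consequence = "synonymous_variant", cadd = 2),
               "low")
  # multiple annotations: the most severe consequence drives the class
  expect_equal(classify1(consequence = "missense_variant&splice_site_variant",
                         spliceai = 0.7), "high")
  expect_error(classify1(consequence = "nonsense_class"),
               class = "hearload_validation_error")
})

test_that("MSC mode uses per-gene cutoffs and drops unscored genes", {
  v <- dplyr::bind_rows(
    make_variants(1, gene_id = "G1", cadd = 20),
    make_variants(1, gene_id = "G2", cadd = 20),
    make_variants(1, gene_id = "G3", cadd = 30))
  v$variant_id <- c("a", "b", "c")
  msc <- tibble::tibble(gene_id = c("G1", "G2"),
                        cadd_cutoff = c(15, 25))
  cl <- classify_impact(v, qc_config(msc_table = msc))
  expect_equal(cl$impact, c("high", "low", NA))
  sel <- select_variants(add_max_external_maf(cl), "high", 0.1,
                         gene_restriction = msc$gene_id)
  expect_equal(sel$variant_id, "a")
})

test_that("variant selection nests across impact and frequency", {
  fx <- small_sim()
  sel_h05 <- select_variants(fx$variants, "high", 0.05, qc = fx$qc)
  sel_h10 <- select_variants(fx$variants, "high", 0.1, qc = fx$qc)
  sel_l10 <- select_variants(fx$variants, "low", 0.1, qc = fx$qc)
  sel_l1 <- select_variants(fx$variants, "low", 1, qc = fx$qc)
  expect_true(all(sel_h05$variant_id %in% sel_h10$variant_id))
  expect_true(all(sel_h10$variant_id %in% sel_l10$variant_id))
  expect_true(all(sel_l10$variant_id %in% sel_l1$variant_id))
  # the vacuous frequency filter keeps every QC-passing variant of the
  # requested impact
  expect_equal(nrow(sel_l1),
               sum(fx$variants$impact[fx$variants$variant_id %in%
                                        fx$qc$variant_id[fx$qc$pass]] %in%
                     c("high", "low") &
                     add_max_external_maf(fx$variants)$max_external_maf[
                       fx$variants$variant_id %in%
                         fx$qc$variant_id[fx$qc$pass]] < 1))
  expect_error(select_variants(fx$variants, "high", 0),
               class = "hearload_validation_error")
})

test_that("hand-built six-variant fixture selects exactly the intended two", {
  v <- tibble::tibble(
    variant_id = sprintf("v%d", 1:6),
    gene_id = "G1", chrom = "chr1", pos = 1:6 * 10L, ref = "A", alt = "G",
    consequence = c("missense_variant", "missense_variant",
                    "missense_variant", "splice_site_variant",
                    "3_prime_UTR_variant", "missense_variant"),
    qual = 100,
    cadd = c(30, 30, 10, 5, 40, 30),     # v3 low CADD, v5 wrong class
    spliceai = c(NA, NA, NA, 0.9, NA, NA),
    sutr = NA_real_, remm = NA_real_,
    af_pop1 = c(0.01, 0.2, 0.01, 0.05, 0.01, NA))
  # v1 passes; v2 too common; v3 low impact; v4 passes via SpliceAI;
  # v5 3' UTR never high; v6 novel (MAF 0) passes
  sel <- select_variants(classify_impact(add_max_external_maf(v)),
                         "high", 0.1)
  expect_setequal(sel$variant_id, c("v1", "v4", "v6"))
  sel_strict <- select_variants(classify_impact(add_max_external_maf(v)),
                                "high", 0.05)
  expect_setequal(sel_strict$variant_id, c("v1", "v6"))
})
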