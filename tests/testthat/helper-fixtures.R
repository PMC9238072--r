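# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# a small spiked cohort exercising the full pipeline quickly
small_sim <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  cfg <- sim_config(n_participants = 300, n_genes = 200,
                    mean_variants_per_gene = 15, n_spiked = 10,
                    deafness_list_size = 40, variable_list_size = 30,
                    seed = 42)
  cohort <- simulate_cohort(cfg)
  calls <- classify_hearing(cohort)
  sim <- simulate_variants(cfg, cohort)
  geno <- mask_calls(sim$geno)
  variants <- add_max_external_maf(sim$variants)
  qc <- site_qc(variants, geno)
  classified <- classify_impact(variants)
  .fixtures$small <- list(cfg = cfg, cohort = cohort, calls = calls,
                          variants = classified, geno = geno, qc = qc,
                          truth = sim$truth,
                          lists = simulate_gene_lists(cfg))
  .fixtures$small
}

# build a one-participant visit table from per-visit answers
make_participant <- function(id = "p1", sex = "male", ages,
                             difficulty = "no", noise_diff = "no",
                             aid = "no", implant = "no", otologic = "no",
                             noise_exp = "no", tinnitus = "none",
                             ethnicity = "White") {
  k <- length(ages)
  rep_k <- function(x) if (length(x) == 1L) rep(x, k) else x
  tibble::tibble(participant_id = id, sex = sex, ethnicity = ethnicity,
                 visit = seq_len(k), age = ages,
                 hearing_difficulty = rep_k(difficulty),
                 difficulty_in_noise = rep_k(noise_diff),
                 hearing_aid = rep_k(aid),
                 cochlear_implant = rep_k(implant),
                 otologic_disorder = rep_k(otologic),
                 noise_exposure_high = rep_k(noise_exp),
                 tinnitus = rep_k(tinnitus))
}

# tiny genotype set from explicit matrices
make_geno <- function(gt, dp = NULL, gq = NULL) {
  if (is.null(dp)) dp <- matrix(30L, nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(99L, nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  dimnames(dp) <- dimnames(gq) <- dimnames(gt)
  list(gt = gt, dp = dp, gq = gq)
}

# minimal annotated variant rows with overridable fields
make_variants <- function(n, gene_id = "G1", consequence = "missense_variant",
                          qual = 100, cadd = NA_real_, spliceai = NA_real_,
                          sutr = NA_real_, remm = NA_real_,
                          af_pop1 = NA_real_) {
  tibble::tibble(variant_id = sprintf("v%02d", seq_len(n)),
                 gene_id = rep_len(gene_id, n),
                 chrom = "chr1", pos = seq_len(n) * 100L,
                 ref = "A", alt = "G",
                 consequence = rep_len(consequence, n),
                 qual = rep_len(qual, n),
                 cadd = rep_len(cadd, n),
                 spliceai = rep_len(spliceai, n),
                 sutr = rep_len(sutr, n),
                 remm = rep_len(remm, n),
                 af_pop1 = rep_len(af_pop1, n))
}

# wrap a residual vector in a load_fit for threshold testing
make_fit <- function(residuals) {
  structure(list(slope = 0, intercept = 0, n = length(residuals),
                 data = tibble::tibble(
                   gene_id = sprintf("g%04d", seq_along(residuals)),
                   load_control = 0, load_case = residuals,
                   fitted = 0, residual = residuals)),
            class = "load_fit")
}

# independent exact Hardy-Weinberg oracle: enumerate every heterozygote
# count compatible with the allele counts and sum the probabilities of
# outcomes no more likely than the observed one
hwe_oracle <- function(n_ref_hom, n_het, n_alt_hom) {
  n_a <- 2 * n_ref_hom + n_het
  n_b <- 2 * n_alt_hom + n_het
  m <- min(n_a, n_b)
  if (m == 0) return(1)
  hs <- seq(m %% 2, m, by = 2)
  probs <- vapply(hs, function(h) {
    exp(lfactorial((n_a + n_b) / 2) - lfactorial((n_a - h) / 2) -
          lfactorial(h) - lfactorial((n_b - h) / 2) +
          lfactorial(n_a) + lfactorial(n_b) - lfactorial(n_a + n_b) +
          h * log(2))
  }, numeric(1))
  obs <- probs[match(n_het, hs)]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# exact rational upper-tail hypergeometric oracle via choose()
hypergeom_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
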