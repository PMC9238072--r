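#' Simulation configuration for a synthetic hearing-difficulty cohort
#'
#' Builds the configuration object consumed by the generators
#' ([simulate_cohort()], [simulate_variants()], [simulate_gene_lists()],
#' [simulate_expression_panel()]). The defaults describe the standard study
#' conditions used throughout the package's tests: a two-group cohort with
#' per-gene variant counts proportional to gene length, a rare-skewed allele
#' frequency spectrum, and a small set of "signal" genes whose high-impact
#' variants carry an elevated alternate-allele probability in the
#' hearing-difficulty group.
#'
#' @param n_participants Number of participants (default 1000).
#' @param n_genes Number of genes in the universe (default 2000).
#' @param mean_variants_per_gene Mean variant count for a gene of average
#'   length; per-gene means scale with simulated gene length (default 60,
#'   giving with the default high-impact fraction roughly 25 high-impact
#'   variants per gene after filtering, the same order of magnitude per
#'   gene as large exome cohorts report).
#' @param maf_shape1,maf_shape2 Shape parameters of the Beta distribution
#'   of true alternate-allele frequencies, truncated to (0, 0.5). The
#'   default Beta(0.2, 4) gives the rare-skewed spectrum the frequency
#'   filters assume.
#' @param n_spiked Number of spiked signal genes (default 20); ignored when
#'   `spiked_gene_ids` is supplied.
#' @param spiked_gene_ids Optional explicit set of spiked gene ids; must be
#'   a subset of the generated universe `sprintf("G%05d", 1:n_genes)`.
#' @param spike_factor Multiplier (>= 1) on the case-group alternate-allele
#'   probability of high-impact variants in spiked genes (default 3).
#' @param spike_all_impacts If `TRUE`, spiking applies to every variant of a
#'   spiked gene, not only high-impact ones (default `FALSE`).
#' @param sex_specific_spiking If `TRUE`, the spiked genes are split into
#'   two halves, one spiked only in male cases and one only in female cases,
#'   emulating sex-specific genetic architecture (default `FALSE`).
#' @param high_impact_fraction Fraction of eligible variants given scores
#'   above the high-impact thresholds (default 0.5).
#' @param missing_rate Fraction of calls given low DP or GQ so they are
#'   masked as missing by call-level QC (default 0.02).
#' @param sex_ratio Fraction of female participants (default 0.5).
#' @param case_fraction Fraction of participants whose questionnaire answers
#'   report hearing difficulty (default 0.5).
#' @param asked_older_fraction Fraction of participants guaranteed a visit
#'   at or above the phenotype age threshold (default 0.97).
#' @param exclusion_rate Rate at which exclusion-triggering answers
#'   (cochlear implant, otologic disorder, reversals, severe tinnitus,
#'   noise exposure) are injected (default 0.03).
#' @param deafness_list_size,variable_list_size Sizes of the synthetic
#'   curated gene lists (defaults 200 and 150).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_participants = 100, n_genes = 50, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n_participants = 1000,
                       n_genes = 2000,
                       mean_variants_per_gene = 60,
                       maf_shape1 = 0.2,
                       maf_shape2 = 4,
                       n_spiked = 20,
                       spiked_gene_ids = NULL,
                       spike_factor = 3,
                       spike_all_impacts = FALSE,
                       sex_specific_spiking = FALSE,
                       high_impact_fraction = 0.5,
                       missing_rate = 0.02,
                       sex_ratio = 0.5,
                       case_fraction = 0.5,
                       asked_older_fraction = 0.97,
                       exclusion_rate = 0.03,
                       deafness_list_size = 200,
                       variable_list_size = 150,
                       seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants")
  n_genes <- check_count(n_genes, "n_genes")
  if (!is.numeric(mean_variants_per_gene) || mean_variants_per_gene <= 0) {
    stop_config("mean_variants_per_gene", "must be positive")
  }
  if (!is.numeric(spike_factor) || length(spike_factor) != 1L ||
      spike_factor < 1) {
    stop_config("spike_factor", "must be a single number >= 1")
  }
  check_fraction(missing_rate, "missing_rate", allow_one = FALSE)
  check_fraction(sex_ratio, "sex_ratio")
  check_fraction(case_fraction, "case_fraction")
  check_fraction(asked_older_fraction, "asked_older_fraction")
  check_fraction(exclusion_rate, "exclusion_rate", allow_one = FALSE)
  check_fraction(high_impact_fraction, "high_impact_fraction")
  seed <- check_count(seed, "seed", min = 0L)

  universe <- sprintf("G%05d", seq_len(n_genes))
  if (is.null(spiked_gene_ids)) {
    n_spiked <- check_count(n_spiked, "n_spiked", min = 0L)
    if (n_spiked > n_genes) {
      stop_config("n_spiked", "cannot exceed n_genes")
    }
    spiked_gene_ids <- with_seed(seed + 104729L,
                                 sample(universe, n_spiked))
  }
  if (!all(spiked_gene_ids %in% universe)) {
    stop_config("spiked_gene_ids", "must be a subset of the gene universe")
  }
  if (deafness_list_size > n_genes) {
    stop_config("deafness_list_size", "cannot exceed the gene universe")
  }
  if (variable_list_size > n_genes - deafness_list_size) {
    stop_config("variable_list_size",
                "deafness and variable lists together exceed the universe")
  }

  structure(list(
    n_participants = n_participants,
    n_genes = n_genes,
    gene_universe = universe,
    mean_variants_per_gene = mean_variants_per_gene,
    maf_shape1 = maf_shape1,
    maf_shape2 = maf_shape2,
    spiked_gene_ids = sort(spiked_gene_ids),
    spike_factor = spike_factor,
    spike_all_impacts = isTRUE(spike_all_impacts),
    sex_specific_spiking = isTRUE(sex_specific_spiking),
    high_impact_fraction = high_impact_fraction,
    missing_rate = missing_rate,
    sex_ratio = sex_ratio,
    case_fraction = case_fraction,
    asked_older_fraction = asked_older_fraction,
    exclusion_rate = exclusion_rate,
    deafness_list_size = deafness_list_size,
    variable_list_size = variable_list_size,
    seed = seed
  ), class = "sim_config")
}

#' Simulate a longitudinal questionnaire cohort
#'
#' Generates one row per participant-visit with exactly the answer fields
#' the phenotype rules read: self-reported hearing difficulty, difficulty in
#' noise, hearing aid and cochlear implant use, otologic disorder, high
#' noise exposure and tinnitus severity. A latent hearing status drives
#' consistent answer patterns; a small configurable fraction of participants
#' receive exclusion-triggering answers so the whole rule set is exercised.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `participant_id`, `sex`, `ethnicity`,
#'   `visit`, `age`, `hearing_difficulty`, `difficulty_in_noise`,
#'   `hearing_aid`, `cochlear_implant`, `otologic_disorder`,
#'   `noise_exposure_high`, `tinnitus`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  with_seed(config$seed + 1L, {
    ids <- sprintf("P%06d", seq_len(n))
    sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")
    ethnicity <- sample(c("White", "Black", "Asian", "Mixed", "Other"), n,
                        replace = TRUE,
                        prob = c(0.90, 0.03, 0.04, 0.02, 0.01))
    latent_case <- runif(n) < config$case_fraction
    n_visits <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
    asked_older <- runif(n) < config$asked_older_fraction

    # exclusion-triggering answer patterns, each at a slice of the rate
    r <- config$exclusion_rate
    excl_kind <- sample(
      c("none", "implant", "otologic", "reversal", "tinnitus", "noise"),
      n, replace = TRUE,
      prob = c(1 - r, r * 0.15, r * 0.25, r * 0.2, r * 0.2, r * 0.2))

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- n_visits[i]
      age0 <- sample(45:66, 1L)
      ages <- cumsum(c(age0, sample(2:6, k - 1L, replace = TRUE)))
      if (asked_older[i] && max(ages) < 55) {
        ages[k] <- sample(55:70, 1L)
      } else if (!asked_older[i]) {
        ages <- pmin(ages, 54L)
      }
      case <- latent_case[i]
      kind <- excl_kind[i]

      if (case) {
        # consistent or worsening difficulty; some are aid users
        onset <- sample(seq_len(k), 1L)
        difficulty <- ifelse(seq_len(k) >= onset, "yes", "no")
        if (onset > 1L && runif(1) < 0.3) difficulty[] <- "yes"
        noise_diff <- ifelse(difficulty == "yes" & runif(k) < 0.7,
                             "yes", "no")
        aid <- if (runif(1) < 0.3) {
          ifelse(seq_len(k) >= sample(seq_len(k), 1L), "yes", "no")
        } else rep("no", k)
        tinnitus <- sample(c("none", "mild", "moderate", "severe"), k,
                           replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
        noise_exp <- rep(sample(c("yes", "no"), 1L, prob = c(0.3, 0.7)), k)
      } else {
        difficulty <- rep("no", k)
        noise_diff <- rep("no", k)
        aid <- rep("no", k)
        tinnitus <- sample(c("none", "mild"), k, replace = TRUE,
                           prob = c(0.8, 0.2))
        noise_exp <- rep("no", k)
      }

      if (kind == "reversal" && k >= 2L) {
        difficulty <- c("yes", rep("no", k - 1L))
        noise_diff <- rep("no", k)
        aid <- rep("no", k)
      } else if (kind == "tinnitus" && !case) {
        tinnitus[k] <- sample(c("moderate", "severe"), 1L)
      } else if (kind == "noise" && !case) {
        noise_exp <- rep("yes", k)
      }
      implant <- rep(if (kind == "implant") "yes" else "no", k)
      otologic <- rep(if (kind == "otologic") "yes" else "no", k)

      # occasional unknown answers, never wiping out every concrete one
      if (k >= 2L && runif(1) < 0.05) {
        j <- sample(seq_len(k - 1L), 1L)
        difficulty[j] <- "unknown"
        noise_diff[j] <- "unknown"
      }

      rows[[i]] <- list(visit = seq_len(k), age = as.numeric(ages),
                        hearing_difficulty = difficulty,
                        difficulty_in_noise = noise_diff,
                        hearing_aid = aid, cochlear_implant = implant,
                        otologic_disorder = otologic,
                        noise_exposure_high = noise_exp,
                        tinnitus = tinnitus)
    }
    pull_field <- function(f) unlist(lapply(rows, `[[`, f))
    tibble::tibble(
      participant_id = rep(ids, n_visits),
      sex = rep(sex, n_visits), ethnicity = rep(ethnicity, n_visits),
      visit = pull_field("visit"), age = pull_field("age"),
      hearing_difficulty = pull_field("hearing_difficulty"),
      difficulty_in_noise = pull_field("difficulty_in_noise"),
      hearing_aid = pull_field("hearing_aid"),
      cochlear_implant = pull_field("cochlear_implant"),
      otologic_disorder = pull_field("otologic_disorder"),
      noise_exposure_high = pull_field("noise_exposure_high"),
      tinnitus = pull_field("tinnitus"))
  })
}

#' Simulate an annotated variant table and genotype matrices
#'
#' Per gene, a variant count is drawn with mean proportional to a simulated
#' gene length. Each variant receives a consequence class from the package
#' vocabulary, deleteriousness scores (CADD, SpliceAI, Sutr, ReMM) sampled
#' so that a configurable fraction is high-impact, external per-population
#' allele frequencies consistent with the true simulation frequency, and a
#' site quality score. Genotypes are drawn as binomial(2, af) in controls
#' and binomial(2, min(af * spike_factor, 1)) in hearing-difficulty cases
#' for high-impact variants of spiked genes. Per-call read depth (DP) and
#' genotype quality (GQ) are simulated with low-quality calls injected at
#' the configured missing rate.
#'
#' Case/control status is taken from the questionnaire answers via
#' [classify_hearing()], so the spiked signal lands exactly on the groups
#' the downstream analysis compares.
#'
#' @param config A [sim_config()] object.
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @return A list with elements `variants` (tibble of annotated variants),
#'   `geno` (list of variants x samples matrices `gt`, `dp`, `gq`) and
#'   `truth` (tibble of spiked gene ids and, under sex-specific spiking,
#'   the sex each gene is spiked in).
#' @export
simulate_variants <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(cohort) == 0L) stop_validation("cohort must be nonempty")

  calls <- classify_hearing(cohort)
  samples <- calls$participant_id
  sample_sex <- cohort |>
    dplyr::distinct(.data$participant_id, .data$sex) |>
    dplyr::pull(.data$sex, name = .data$participant_id)
  is_case <- calls$group == "difficulty"

  with_seed(config$seed + 2L, {
    genes <- tibble::tibble(
      gene_id = config$gene_universe,
      length = exp(rnorm(config$n_genes, log(2200), 0.3)))
    lambda <- config$mean_variants_per_gene * genes$length /
      mean(genes$length)
    n_var <- rpois(config$n_genes, lambda)

    gene_of <- rep(genes$gene_id, n_var)
    nv <- length(gene_of)
    vocab <- consequence_vocabulary()
    cons_prob <- c(stop_gained = 0.03, stop_lost = 0.005, start_lost = 0.005,
                   frameshift_variant = 0.03, splice_site_variant = 0.05,
                   inframe_insertion = 0.01, inframe_deletion = 0.01,
                   missense_variant = 0.45, mature_miRNA_variant = 0.005,
                   `5_prime_UTR_variant` = 0.06, `3_prime_UTR_variant` = 0.08,
                   synonymous_variant = 0.20,
                   regulatory_region_variant = 0.04, intron_variant = 0.025,
                   intergenic_variant = 0.005)
    consequence <- sample(names(cons_prob), nv, replace = TRUE,
                          prob = cons_prob)
    category <- consequence_category(consequence)

    af <- pmin(pmax(rbeta(nv, config$maf_shape1, config$maf_shape2), 1e-4),
               0.4999)

    hi_draw <- runif(nv) < config$high_impact_fraction
    cadd <- ifelse(category %in% c("coding", "miRNA"),
                   ifelse(hi_draw, runif(nv, 25.5, 45), runif(nv, 0, 24.5)),
                   runif(nv, 0, 20))
    spliceai <- ifelse(category == "splice",
                       ifelse(hi_draw, runif(nv, 0.55, 1), runif(nv, 0, 0.45)),
                       runif(nv, 0, 0.2))
    sutr <- ifelse(category == "utr5",
                   ifelse(hi_draw, runif(nv, 1.1, 4), runif(nv, 0, 0.9)),
                   runif(nv, 0, 0.5))
    remm <- ifelse(category == "other",
                   ifelse(runif(nv) < 0.3, runif(nv, 0.96, 1),
                          runif(nv, 0, 0.9)),
                   runif(nv, 0, 0.9))
    qual <- ifelse(runif(nv) < 0.01, runif(nv, 5, 19.5), runif(nv, 30, 2000))

    # external panels report the generating frequency plus sampling noise
    pops <- c("gnomad_nfe", "gnomad_afr", "gnomad_eas", "kg_eur", "topmed")
    ext <- lapply(pops, function(p) {
      se <- sqrt(af * (1 - af) / (2 * 20000))
      pmin(pmax(af + rnorm(nv, 0, se), 0), 1)
    })
    names(ext) <- paste0("af_", pops)
    novel <- runif(nv) < 0.03
    for (p in names(ext)) ext[[p]][novel] <- NA_real_

    chrom_of_gene <- paste0("chr", rep_len(1:22, config$n_genes))
    names(chrom_of_gene) <- genes$gene_id

    variants <- tibble::tibble(
      variant_id = sprintf("V%07d", seq_len(nv)),
      gene_id = gene_of,
      chrom = chrom_of_gene[gene_of],
      pos = stats::ave(seq_len(nv), gene_of, FUN = seq_along) * 150L +
        1000L,
      ref = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
      consequence = consequence,
      qual = qual,
      cadd = cadd, spliceai = spliceai, sutr = sutr, remm = remm,
      true_af = af,
      !!!ext)
    same <- variants$ref == variants$alt
    variants$alt[same] <- chartr("ACGT", "CGTA", variants$ref[same])

    ns <- length(samples)
    gt <- matrix(rbinom(nv * ns, 2L, af), nrow = nv, ncol = ns,
                 dimnames = list(variants$variant_id, samples))

    # spike case-group genotype probabilities
    spike_rows <- gene_of %in% config$spiked_gene_ids &
      (config$spike_all_impacts | hi_draw)
    truth <- tibble::tibble(gene_id = config$spiked_gene_ids,
                            spiked_sex = "both")
    if (config$spike_factor > 1 && any(spike_rows) && any(is_case)) {
      if (config$sex_specific_spiking) {
        half <- ceiling(length(config$spiked_gene_ids) / 2)
        male_genes <- config$spiked_gene_ids[seq_len(half)]
        female_genes <- setdiff(config$spiked_gene_ids, male_genes)
        truth$spiked_sex <-
          ifelse(truth$gene_id %in% male_genes, "male", "female")
        for (sx in c("male", "female")) {
          g <- if (sx == "male") male_genes else female_genes
          rows <- which(spike_rows & gene_of %in% g)
          cols <- which(is_case & sample_sex[samples] == sx)
          if (length(rows) && length(cols)) {
            p <- pmin(af[rows] * config$spike_factor, 1)
            gt[rows, cols] <- rbinom(length(rows) * length(cols), 2L, p)
          }
        }
      } else {
        rows <- which(spike_rows)
        cols <- which(is_case)
        p <- pmin(af[rows] * config$spike_factor, 1)
        gt[rows, cols] <- rbinom(length(rows) * length(cols), 2L, p)
      }
    }

    # passing calls get DP and GQ comfortably above the QC minima; the
    # low-quality calls that drive missingness are injected below
    dp <- matrix(sample.int(51L, nv * ns, replace = TRUE) + 19L,
                 nrow = nv, ncol = ns, dimnames = dimnames(gt))
    gq <- matrix(sample.int(80L, nv * ns, replace = TRUE) + 19L,
                 nrow = nv, ncol = ns, dimnames = dimnames(gt))
    n_bad <- rbinom(1L, nv * ns, config$missing_rate)
    if (n_bad > 0L) {
      bad <- sample.int(nv * ns, n_bad)
      half <- bad[seq_len(floor(n_bad / 2))]
      rest <- setdiff(bad, half)
      dp[half] <- sample(0:9, length(half), replace = TRUE)
      gq[rest] <- sample(0:9, length(rest), replace = TRUE)
    }

    list(variants = variants,
         geno = list(gt = gt, dp = dp, gq = gq),
         truth = truth)
  })
}

#' Simulate curated gene lists
#'
#' Builds a synthetic "deafness gene" list containing every spiked gene plus
#' random decoys, and a "highly variable gene" list disjoint from the spiked
#' genes, both drawn from the configured gene universe.
#'
#' @param config A [sim_config()] object.
#' @return A `gene_list_set`: list with `universe` (character vector) and
#'   `lists` (named list of character vectors).
#' @export
simulate_gene_lists <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    spiked <- config$spiked_gene_ids
    pool <- setdiff(config$gene_universe, spiked)
    n_decoy <- config$deafness_list_size - length(spiked)
    if (n_decoy < 0L) {
      stop_config("deafness_list_size",
                  "must be at least the number of spiked genes")
    }
    deafness <- sort(c(spiked, sample(pool, n_decoy)))
    variable <- sort(sample(setdiff(pool, deafness),
                            config$variable_list_size))
    gene_list_set(universe = config$gene_universe,
                  lists = list(deafness = deafness, variable = variable))
  })
}

#' Simulate an inner-ear expression panel
#'
#' Generates several gene-by-cell-type expression datasets over a shared
#' cell-type vocabulary, with marker genes expressed highly in exactly one
#' cell-type group, a housekeeping reference gene present in all datasets,
#' and one dataset whose reference expression is zero so the downstream
#' exclusion rule is exercised.
#'
#' @param config A [sim_config()] object.
#' @param n_marker_genes Number of cell-type marker genes (default 40).
#' @param n_background_genes Number of non-specific genes (default 20).
#' @return A list of `expression_dataset` objects (see
#'   [expression_dataset()]).
#' @export
simulate_expression_panel <- function(config, n_marker_genes = 40,
                                      n_background_genes = 20) {
  stopifnot(inherits(config, "sim_config"))
  groups <- cochlear_cell_groups()
  cell_types <- names(groups)
  with_seed(config$seed + 4L, {
    n_genes <- n_marker_genes + n_background_genes
    gene_ids <- config$gene_universe[seq_len(min(n_genes,
                                                 config$n_genes))]
    marker_ids <- gene_ids[seq_len(min(n_marker_genes, length(gene_ids)))]
    bg_ids <- setdiff(gene_ids, marker_ids)
    home_group <- sample(unique(unname(groups)), length(marker_ids),
                         replace = TRUE)

    base <- matrix(runif(length(gene_ids) * length(cell_types), 0.1, 1.5),
                   nrow = length(gene_ids),
                   dimnames = list(gene_ids, cell_types))
    for (i in seq_along(marker_ids)) {
      home_cells <- cell_types[groups == home_group[i]]
      base[marker_ids[i], home_cells] <-
        runif(length(home_cells), 20, 60)
    }

    stages <- c("E16", "P7", "P20", "P30")
    datasets <- lapply(seq_along(stages), function(d) {
      keep_cells <- if (d %% 2L == 0L) cell_types else
        sample(cell_types, max(3L, length(cell_types) - 2L))
      noise <- matrix(runif(length(gene_ids) * length(keep_cells),
                            0.8, 1.2),
                      nrow = length(gene_ids))
      mat <- base[, keep_cells, drop = FALSE] * noise
      ref_value <- if (d == length(stages)) 0 else runif(1, 0.8, 2)
      mat <- rbind(mat, Hprt = rep(ref_value, ncol(mat)))
      expression_dataset(dataset_id = sprintf("ds_%s", stages[d]),
                         stage = stages[d], mat = mat,
                         reference_gene = "Hprt")
    })
    attr(datasets, "marker_truth") <-
      tibble::tibble(gene_id = marker_ids, home_group = home_group)
    datasets
  })
}

#' Default cochlear cell-type grouping
#'
#' Maps individual cochlear cell types to broader anatomical groups (hair
#' cells, supporting cells, lateral wall, spiral ganglion neurons,
#' Reissner's membrane) used when describing expression clusters.
#'
#' @return Named character vector: names are cell types, values are groups.
#' @export
cochlear_cell_groups <- function() {
  c(IHC = "HC", OHC = "HC",
    pillar_cells = "SC", Deiters_cells = "SC", Hensen_cells = "SC",
    marginal_cells = "LW", intermediate_cells = "LW", basal_cells = "LW",
    fibrocytes = "LW",
    SGN = "SGN",
    Reissners_membrane = "RM")
}
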