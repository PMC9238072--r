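#' Study configuration
#'
#' Defines the grid of analysis cells (impact level x MAF cutoff x sex
#' stratum) the study runs, plus the outlier rule and burden settings.
#'
#' @param maf_cutoffs Frequency cutoffs; default the six-cutoff ladder
#'   `c(0.005, 0.01, 0.05, 0.1, 0.2, 1)`.
#' @param impacts Impact levels to run; default `c("high", "low")`.
#' @param strata Sex strata; default `c("all", "male", "female")`.
#' @param multiplier Outlier threshold multiplier (default 6).
#' @param counting_mode `"alleles"` or `"carriers"` (default alleles).
#' @param min_age Phenotype age threshold (default 55).
#' @param burden_cells A tibble with columns `impact`, `maf_cutoff`,
#'   `stratum` naming the cells on which the weighted burden test also
#'   runs; defaults to the high-impact, MAF < 0.1, all-participants cell.
#' @param qc A [qc_config()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(maf_cutoffs = c(0.005, 0.01, 0.05, 0.1, 0.2, 1),
                         impacts = c("high", "low"),
                         strata = c("all", "male", "female"),
                         multiplier = 6,
                         counting_mode = "alleles",
                         min_age = 55,
                         burden_cells = NULL,
                         qc = qc_config()) {
  if (length(maf_cutoffs) == 0L) {
    stop_config("maf_cutoffs", "must contain at least one cutoff")
  }
  if (any(maf_cutoffs <= 0 | maf_cutoffs > 1)) {
    stop_config("maf_cutoffs", "cutoffs must lie in (0, 1]")
  }
  impacts <- match.arg(impacts, c("high", "low"), several.ok = TRUE)
  strata <- match.arg(strata, c("all", "male", "female"),
                      several.ok = TRUE)
  if (is.null(burden_cells)) {
    burden_cells <- tibble::tibble(impact = "high", maf_cutoff = 0.1,
                                   stratum = "all")
  }
  structure(list(maf_cutoffs = sort(maf_cutoffs), impacts = impacts,
                 strata = strata, multiplier = multiplier,
                 counting_mode = counting_mode, min_age = min_age,
                 burden_cells = burden_cells, qc = qc),
            class = "study_config")
}

#' Run the full variant-load study
#'
#' Orchestrates the pipeline: phenotype classification, call masking and
#' site QC (done once), then for every requested (impact x MAF cutoff x
#' stratum) cell a variant selection, per-gene load regression, outlier
#' detection and gene-list enrichment; the weighted burden test runs on the
#' configured cells. Failures in one cell are recorded without aborting the
#' others. Randomness lives entirely in the synthetic-data generators:
#' given identical inputs the report is identical.
#'
#' @param config A [study_config()].
#' @param cohort Cohort visit tibble.
#' @param variants Annotated variant tibble.
#' @param geno Genotype list (`gt`, `dp`, `gq`).
#' @param gene_lists A [gene_list_set()] providing the gene universe and
#'   the reference lists (e.g. `deafness`, `variable`) the outlier lists
#'   are tested against.
#' @param msc_table Optional gene-specific CADD cutoff table; when given,
#'   an additional MSC-mode analysis restricted to its genes runs for each
#'   stratum at the MSC MAF cutoff (0.1).
#' @return An object of class `study_report`: list with `summary` (one
#'   row per cell: list sizes and enrichment results), `cells` (named list
#'   holding each cell's `outlier_result` or error message), `burden`
#'   (named list of SLP rankings), `phenotype` (classification summary)
#'   and `m` (the Bonferroni family size used for every adjusted p).
#' @export
run_study <- function(config, cohort, variants, geno, gene_lists,
                      msc_table = NULL) {
  stopifnot(inherits(config, "study_config"),
            inherits(gene_lists, "gene_list_set"))

  calls <- classify_hearing(cohort, min_age = config$min_age)
  geno <- mask_calls(geno, config$qc)
  variants <- add_max_external_maf(variants)
  qc <- site_qc(variants, geno, config$qc)
  classified <- classify_impact(variants, config$qc)

  grid <- tidyr::expand_grid(impact = config$impacts,
                             maf_cutoff = config$maf_cutoffs,
                             stratum = config$strata,
                             msc = FALSE)
  if (!is.null(msc_table)) {
    grid <- dplyr::bind_rows(grid, tidyr::expand_grid(
      impact = "high", maf_cutoff = 0.1, stratum = config$strata,
      msc = TRUE))
  }

  # every enrichment (cells x two outlier directions x reference lists)
  # belongs to one Bonferroni family, recorded in the report
  m <- nrow(grid) * 2L * length(gene_lists$lists)

  msc_classified <- if (!is.null(msc_table)) {
    classify_impact(variants, qc_config_with_msc(config$qc, msc_table))
  } else NULL

  cells <- vector("list", nrow(grid))
  names(cells) <- sprintf("%s_maf%s_%s%s", grid$impact, grid$maf_cutoff,
                          grid$stratum, ifelse(grid$msc, "_msc", ""))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    res <- tryCatch({
      v <- if (cell$msc) {
        select_variants(msc_classified, impact = cell$impact,
                        maf_cutoff = cell$maf_cutoff, qc = qc,
                        gene_restriction = msc_table$gene_id)
      } else {
        select_variants(classified, impact = cell$impact,
                        maf_cutoff = cell$maf_cutoff, qc = qc)
      }
      universe <- if (cell$msc) {
        intersect(gene_lists$universe, msc_table$gene_id)
      } else gene_lists$universe
      stratified_load_outliers(
        v, geno, calls, cohort, strata = cell$stratum,
        universe = universe, counting_mode = config$counting_mode,
        multiplier = config$multiplier)[[cell$stratum]]
    }, error = function(e) e)
    cells[[i]] <- res

    if (inherits(res, "error")) {
      rows[[i]] <- dplyr::mutate(cell, error = conditionMessage(res))
      next
    }
    universe <- if (cell$msc) {
      intersect(gene_lists$universe, msc_table$gene_id)
    } else gene_lists$universe
    enr <- purrr::imap(gene_lists$lists, function(ref, ref_name) {
      ref <- intersect(ref, universe)  # MSC cells shrink the universe
      dplyr::bind_rows(
        case = enrich(res$outliers_case, ref, universe, m = m),
        control = enrich(res$outliers_control, ref, universe, m = m),
        .id = "direction") |>
        dplyr::mutate(reference = ref_name, .before = 1L)
    }) |> dplyr::bind_rows()
    rows[[i]] <- dplyr::mutate(
      cell,
      n_outliers_case = length(res$outliers_case),
      n_outliers_control = length(res$outliers_control),
      enrichment = list(enr), error = NA_character_)
  }
  summary <- dplyr::bind_rows(rows)

  burden <- purrr::pmap(config$burden_cells, function(impact, maf_cutoff,
                                                      stratum) {
    v <- select_variants(classified, impact = impact,
                         maf_cutoff = maf_cutoff, qc = qc)
    keep <- if (stratum == "all") calls$participant_id else {
      sex_of <- cohort |>
        dplyr::distinct(.data$participant_id, .data$sex) |>
        dplyr::pull(.data$sex, name = .data$participant_id)
      calls$participant_id[sex_of[calls$participant_id] == stratum]
    }
    sub_calls <- dplyr::filter(calls, .data$participant_id %in% keep)
    sub_geno <- list(gt = geno$gt[, intersect(colnames(geno$gt), keep),
                                  drop = FALSE])
    scores <- subject_gene_scores(
      v, sub_geno, burden_config(maf_cap = min(maf_cutoff, 0.5)))
    rank_by_slp(burden_test(scores, sub_calls))
  })
  names(burden) <- sprintf("%s_maf%s_%s", config$burden_cells$impact,
                           config$burden_cells$maf_cutoff,
                           config$burden_cells$stratum)

  structure(list(summary = summary, cells = cells, burden = burden,
                 phenotype = summarize_groups(calls, cohort,
                                              config$min_age),
                 calls = calls, qc = qc, m = m, config = config),
            class = "study_report")
}

qc_config_with_msc <- function(qc, msc_table) {
  qc$msc_table <- msc_table
  qc
}

#' @export
print.study_report <- function(x, ...) {
  ok <- sum(is.na(x$summary$error))
  cat(sprintf(
    "<study_report> %d/%d analysis cells completed; Bonferroni m = %d\n",
    ok, nrow(x$summary), x$m))
  print(dplyr::select(x$summary, dplyr::any_of(c(
    "impact", "maf_cutoff", "stratum", "msc", "n_outliers_case",
    "n_outliers_control", "error"))))
  invisible(x)
}
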