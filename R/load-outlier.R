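#' Per-gene variant load by phenotype group
#'
#' Sums qualifying variant alleles (or carriers) per gene within the normal
#' hearing and hearing difficulty groups. Missing calls contribute zero.
#' Genes in `universe` with no surviving variants are retained with zero
#' loads: they anchor the regression intercept.
#'
#' @param variants Filtered variant tibble (e.g. from [select_variants()])
#'   with columns `variant_id` and `gene_id`.
#' @param geno Genotype list; `gt` is a variants x samples matrix, ideally
#'   masked by [mask_calls()].
#' @param calls Phenotype calls from [classify_hearing()]; every sample in
#'   `geno` must be classified. Excluded participants are ignored.
#' @param counting_mode `"alleles"` (a homozygote counts 2) or
#'   `"carriers"` (any non-reference genotype counts 1).
#' @param universe Optional character vector of gene ids defining the
#'   analysis universe; defaults to the genes present in `variants`.
#' @return A tibble (one row per universe gene) with `gene_id`,
#'   `load_control`, `load_case`, and attributes `n_control`, `n_case`
#'   and `counting_mode`.
#' @export
per_gene_load <- function(variants, geno,
                          calls, counting_mode = c("alleles", "carriers"),
                          universe = NULL) {
  counting_mode <- match.arg(counting_mode)
  gt <- check_geno_matrix(geno$gt)
  unknown <- setdiff(colnames(gt), calls$participant_id)
  if (length(unknown)) {
    stop_validation(sprintf(
      "samples without a phenotype call: %s",
      paste(head(unknown, 5L), collapse = ", ")))
  }
  universe <- sort(unique(c(universe, variants$gene_id)))

  controls <- calls$participant_id[calls$group == "normal"]
  cases <- calls$participant_id[calls$group == "difficulty"]
  controls <- intersect(colnames(gt), controls)
  cases <- intersect(colnames(gt), cases)

  loads <- tibble::tibble(gene_id = universe, load_control = 0,
                          load_case = 0)
  if (nrow(variants) > 0L) {
    g <- gt[variants$variant_id, , drop = FALSE]
    g[is.na(g)] <- 0L
    if (counting_mode == "carriers") g <- (g > 0L) + 0L
    per_gene <- rowsum(g, group = variants$gene_id)
    idx <- match(rownames(per_gene), universe)
    loads$load_control[idx] <- rowSums(per_gene[, controls, drop = FALSE])
    loads$load_case[idx] <- rowSums(per_gene[, cases, drop = FALSE])
  }
  attr(loads, "n_control") <- length(controls)
  attr(loads, "n_case") <- length(cases)
  attr(loads, "counting_mode") <- counting_mode
  loads
}

#' Regress hearing-difficulty load on normal-hearing load
#'
#' Ordinary least squares with intercept, computed from the closed-form
#' normal equations: the per-gene variant load in the hearing difficulty
#' group (response) against the load in the normal hearing group
#' (predictor). The per-gene residual is the observed minus the predicted
#' load in hearing difficulty.
#'
#' @param loads A gene load tibble from [per_gene_load()] (columns
#'   `gene_id`, `load_control`, `load_case`).
#' @return An object of class `load_fit`: list with `slope`, `intercept`,
#'   `n` and `data` (the input plus `fitted` and `residual` columns).
#' @examples
#' loads <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                         load_control = c(1, 2, 3),
#'                         load_case = c(2, 4, 6))
#' fit_load_regression(loads)  # slope 2, intercept 0
#' @export
fit_load_regression <- function(loads) {
  if (nrow(loads) < 3L) {
    stop_validation("need at least 3 genes to fit the load regression")
  }
  x <- as.numeric(loads$load_control)
  y <- as.numeric(loads$load_case)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    stop_validation(paste(
      "control loads are all identical; the regression is degenerate.",
      "Consider per-capita normalization or a larger gene universe."))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  structure(list(slope = slope, intercept = intercept, n = length(x),
                 data = dplyr::mutate(loads, fitted = fitted,
                                      residual = y - fitted)),
            class = "load_fit")
}

#' @export
print.load_fit <- function(x, ...) {
  cat(sprintf(
    "<load_fit> %d genes; case load = %.4f + %.4f * control load\n",
    x$n, x$intercept, x$slope))
  invisible(x)
}

#' Detect outlier genes by the interquartile-range residual rule
#'
#' Computes the first and third quartiles (Q1, Q3) of the regression
#' residuals and the interquartile distance D = Q3 - Q1. Genes with
#' residuals strictly above Q3 + multiplier * D have a high variant load in
#' hearing difficulty; genes strictly below Q1 - multiplier * D have a high
#' variant load in normal hearing.
#'
#' @param fit A `load_fit` from [fit_load_regression()].
#' @param multiplier Threshold multiplier on D (default 6).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, the R default linear interpolation).
#' @return An object of class `outlier_result`: list with `q1`, `q3`, `d`,
#'   `upper_threshold`, `lower_threshold`, `multiplier`, `outliers_case`
#'   and `outliers_control` (character vectors of gene ids) and `data`.
#' @export
detect_outliers <- function(fit, multiplier = 6, quantile_type = 7) {
  stopifnot(inherits(fit, "load_fit"))
  if (!is.numeric(multiplier) || multiplier < 0) {
    stop_validation("multiplier must be nonnegative")
  }
  r <- fit$data$residual
  if (length(r) < 4L) {
    stop_validation("need at least 4 residuals for quartile thresholds")
  }
  q <- quantile(r, c(0.25, 0.75), type = quantile_type, names = FALSE)
  d <- q[2] - q[1]
  upper <- q[2] + multiplier * d
  lower <- q[1] - multiplier * d
  data <- dplyr::mutate(fit$data, outlier = dplyr::case_when(
    .data$residual > upper ~ "case",
    .data$residual < lower ~ "control",
    TRUE ~ "none"))
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 q1 = q[1], q3 = q[2], d = d,
                 upper_threshold = upper, lower_threshold = lower,
                 multiplier = multiplier,
                 outliers_case = data$gene_id[data$outlier == "case"],
                 outliers_control = data$gene_id[data$outlier == "control"],
                 data = data),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf(
    paste0("<outlier_result> %d genes; Q1 = %.3f, Q3 = %.3f, D = %.3f\n",
           "  %d outliers with high load in hearing difficulty,",
           " %d with high load in normal hearing\n"),
    nrow(x$data), x$q1, x$q3, x$d,
    length(x$outliers_case), length(x$outliers_control)))
  invisible(x)
}

#' Normalised variant-type summary for outlier gene lists
#'
#' For each gene list and phenotype group, counts alleles per consequence
#' class (taking the most severe consequence of each variant) and
#' normalises per person and per gene in the list.
#'
#' @param variants Filtered variant tibble (columns `variant_id`,
#'   `gene_id`, `consequence`).
#' @param geno Genotype list (masked).
#' @param calls Phenotype calls from [classify_hearing()].
#' @param gene_lists Named list of character vectors of gene ids, e.g.
#'   `list(case = res$outliers_case, control = res$outliers_control)`.
#' @return A tibble with `list`, `group`, `consequence`, `count`,
#'   `n_people`, `n_genes` and `rate` (count / (people x genes)). Empty
#'   lists yield no rows.
#' @export
summarize_variant_types <- function(variants, geno, calls, gene_lists) {
  gt <- check_geno_matrix(geno$gt)
  groups <- list(
    normal = intersect(colnames(gt),
                       calls$participant_id[calls$group == "normal"]),
    difficulty = intersect(colnames(gt),
                           calls$participant_id[calls$group == "difficulty"]))
  variants <- dplyr::mutate(
    variants, severe = most_severe_consequence(.data$consequence))

  out <- purrr::imap(gene_lists, function(genes, list_name) {
    v <- dplyr::filter(variants, .data$gene_id %in% genes)
    if (nrow(v) == 0L || length(genes) == 0L) return(NULL)
    g <- gt[v$variant_id, , drop = FALSE]
    g[is.na(g)] <- 0L
    purrr::imap(groups, function(samples, group_name) {
      counts <- rowSums(g[, samples, drop = FALSE])
      tibble::tibble(list = list_name, group = group_name,
                     consequence = v$severe, count = counts) |>
        dplyr::group_by(.data$list, .data$group, .data$consequence) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
        dplyr::mutate(n_people = length(samples),
                      n_genes = length(genes),
                      rate = .data$count / (.data$n_people * .data$n_genes))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble::tibble(list = character(), group = character(),
                          consequence = character(), count = numeric(),
                          n_people = integer(), n_genes = integer(),
                          rate = numeric()))
  }
  dplyr::arrange(out, .data$list, .data$group,
                 consequence_rank(.data$consequence))
}

#' Sex-stratified load regression and outlier detection
#'
#' Runs the full load/regression/outlier analysis independently on the
#' requested strata (`all`, `male`, `female` participants).
#'
#' @param variants Filtered variant tibble.
#' @param geno Genotype list (masked).
#' @param calls Phenotype calls from [classify_hearing()].
#' @param cohort Cohort tibble carrying `participant_id` and `sex`.
#' @param strata Character vector among `"all"`, `"male"`, `"female"`.
#' @param universe Optional gene universe (see [per_gene_load()]).
#' @param counting_mode,multiplier,quantile_type Passed through to
#'   [per_gene_load()] and [detect_outliers()].
#' @return Named list of `outlier_result`, one per stratum.
#' @export
stratified_load_outliers <- function(variants, geno, calls, cohort,
                                     strata = c("all", "male", "female"),
                                     universe = NULL,
                                     counting_mode = "alleles",
                                     multiplier = 6, quantile_type = 7) {
  strata <- match.arg(strata, several.ok = TRUE)
  sex_of <- cohort |>
    dplyr::distinct(.data$participant_id, .data$sex) |>
    dplyr::pull(.data$sex, name = .data$participant_id)
  if (!all(calls$participant_id %in% names(sex_of))) {
    stop_validation("sex is missing for some classified participants")
  }

  purrr::map(setNames(strata, strata), function(s) {
    keep <- if (s == "all") calls$participant_id else
      calls$participant_id[sex_of[calls$participant_id] == s]
    sub_calls <- dplyr::filter(calls, .data$participant_id %in% keep)
    n_per_group <- table(factor(sub_calls$group,
                                levels = c("normal", "difficulty")))
    if (any(n_per_group < 2L)) {
      stop_validation(sprintf(
        "stratum `%s` has fewer than 2 participants in a phenotype group", s))
    }
    sub_geno <- list(gt = geno$gt[, intersect(colnames(geno$gt), keep),
                                  drop = FALSE])
    loads <- per_gene_load(variants, sub_geno, sub_calls,
                           counting_mode = counting_mode,
                           universe = universe)
    detect_outliers(fit_load_regression(loads), multiplier = multiplier,
                    quantile_type = quantile_type)
  })
}
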