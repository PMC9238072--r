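#' Tidy a load regression fit
#'
#' @param x A `load_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`intercept`, `slope`).
#' @exportS3Method generics::tidy
tidy.load_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' Glance at a load regression fit
#'
#' @param x A `load_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`, `sigma`,
#'   `n`.
#' @exportS3Method generics::glance
glance.load_fit <- function(x, ...) {
  y <- x$data$load_case
  rss <- sum(x$data$residual^2)
  tss <- sum((y - mean(y))^2)
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 sigma = sqrt(rss / max(1, x$n - 2)), n = x$n)
}

#' Tidy an outlier detection result
#'
#' @param x An `outlier_result`.
#' @param ... Unused.
#' @return The per-gene tibble with loads, residuals and outlier side.
#' @exportS3Method generics::tidy
tidy.outlier_result <- function(x, ...) {
  x$data
}

#' Glance at an outlier detection result
#'
#' @param x An `outlier_result`.
#' @param ... Unused.
#' @return A one-row tibble with quartiles, thresholds and list sizes.
#' @exportS3Method generics::glance
glance.outlier_result <- function(x, ...) {
  tibble::tibble(q1 = x$q1, q3 = x$q3, d = x$d,
                 upper_threshold = x$upper_threshold,
                 lower_threshold = x$lower_threshold,
                 multiplier = x$multiplier,
                 n_outliers_case = length(x$outliers_case),
                 n_outliers_control = length(x$outliers_control),
                 n_genes = nrow(x$data))
}

#' Tidy a study report
#'
#' Unnests the per-cell enrichment results into one row per analysis cell,
#' outlier direction and reference list.
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A tibble with columns `impact`, `maf_cutoff`, `stratum`,
#'   `msc`, list sizes and the enrichment statistics.
#' @exportS3Method generics::tidy
tidy.study_report <- function(x, ...) {
  x$summary |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::select(-"error") |>
    tidyr::unnest("enrichment")
}

#' Glance at a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of cells, failures, the Bonferroni
#'   family size `m`, and phenotype group sizes.
#' @exportS3Method generics::glance
glance.study_report <- function(x, ...) {
  counts <- x$phenotype$by_sex |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  n_of <- function(g) {
    v <- counts$n[counts$group == g]
    if (length(v)) v else 0L
  }
  tibble::tibble(n_cells = nrow(x$summary),
                 n_failed = sum(!is.na(x$summary$error)),
                 m = x$m,
                 n_normal = n_of("normal"),
                 n_difficulty = n_of("difficulty"),
                 n_excluded = n_of("excluded"))
}
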