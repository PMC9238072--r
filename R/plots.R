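#' Scatter plot of per-gene variant loads with outliers highlighted
#'
#' Each point is a gene: normal-hearing load on the x axis, hearing
#' difficulty load on the y axis, the fitted regression line, and outliers
#' coloured by direction.
#'
#' @param result An `outlier_result` from [detect_outliers()].
#' @param drop_extremes Optionally drop the genes with the largest control
#'   loads before plotting (count; default 0) to mirror the usual zoomed
#'   view that omits the few extreme-count genes.
#' @return A ggplot object.
#' @export
plot_load_regression <- function(result, drop_extremes = 0) {
  stopifnot(inherits(result, "outlier_result"))
  data <- result$data
  if (drop_extremes > 0) {
    data <- dplyr::slice_min(data, .data$load_control,
                             n = nrow(data) - drop_extremes,
                             with_ties = FALSE)
  }
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$load_control,
                               y = .data$load_case,
                               colour = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = result$slope,
                         intercept = result$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(none = "grey60", case = "darkorange", control = "steelblue"),
      labels = c(none = "not outlier",
                 case = "high load in hearing difficulty",
                 control = "high load in normal hearing")) +
    ggplot2::labs(x = "Variant load, normal hearing",
                  y = "Variant load, hearing difficulty",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.outlier_result <- function(object, ...) {
  plot_load_regression(object, ...)
}

#' SLP ranking plot for burden results
#'
#' Genes ordered by signed log p value, with the +/- threshold lines.
#'
#' @param ranking Output of [rank_by_slp()].
#' @param threshold SLP threshold drawn (default 2).
#' @return A ggplot object.
#' @export
plot_slp_ranking <- function(ranking, threshold = 2) {
  ggplot2::ggplot(ranking$ranked,
                  ggplot2::aes(x = .data$rank, y = .data$slp)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Gene rank", y = "Signed log p (SLP)") +
    ggplot2::theme_minimal()
}

#' Expression heatmap in dendrogram order
#'
#' Tile heatmap of the scaled gene x cell-type matrix, rows and columns
#' ordered by the hierarchical clustering dendrograms.
#'
#' @param clustering A `gene_clusters` object from [cluster_genes()].
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(clustering) {
  stopifnot(inherits(clustering, "gene_clusters"))
  mat <- clustering$mat
  row_order <- rownames(mat)[clustering$gene_tree$order]
  col_order <- if (!is.null(clustering$cell_tree)) {
    colnames(mat)[clustering$cell_tree$order]
  } else colnames(mat)
  long <- tibble::as_tibble(mat, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell_type",
                        values_to = "level") |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = row_order),
                  cell_type = factor(.data$cell_type, levels = col_order))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type,
                                     y = .data$gene_id,
                                     fill = .data$level)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("lightyellow", "yellow", "orange", "red"),
      values = scales_rescale(c(0, 1, 2, 3)),
      na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# rescale breakpoints to [0, 1] for scale_fill_gradientn
scales_rescale <- function(x) (x - min(x)) / (max(x) - min(x))

#' @exportS3Method ggplot2::autoplot
autoplot.gene_clusters <- function(object, ...) {
  plot_expression_heatmap(object)
}
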