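#' Expression dataset
#'
#' One gene-by-cell-type matrix of nonnegative expression values from a
#' single source (e.g. one single-cell RNAseq study collapsed to cell-type
#' means), together with its developmental stage label and the housekeeping
#' reference gene used for normalisation.
#'
#' @param dataset_id Identifier.
#' @param stage Stage label (e.g. `"P7"`).
#' @param mat Numeric gene x cell-type matrix with dimnames.
#' @param reference_gene Reference gene id (default `"Hprt"`).
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, stage, mat,
                               reference_gene = "Hprt") {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_validation("mat must be a gene x cell-type matrix with dimnames")
  }
  if (any(mat < 0, na.rm = TRUE)) {
    stop_validation("expression values must be nonnegative")
  }
  structure(list(dataset_id = dataset_id, stage = stage, mat = mat,
                 reference_gene = reference_gene, excluded = FALSE),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s (%s): %d genes x %d cell types%s\n",
              x$dataset_id, x$stage, nrow(x$mat), ncol(x$mat),
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

#' Normalise a dataset to its reference gene
#'
#' Divides every expression value by the dataset's reference-gene level
#' (the mean of the reference gene's row across cell types). When the
#' reference gene is absent from the dataset or has expression 0, the
#' dataset is marked excluded rather than normalised; exclusion is a
#' result, not an error.
#'
#' @param dataset An [expression_dataset()].
#' @return The dataset, normalised (reference row removed) or with
#'   `excluded = TRUE`.
#' @export
normalize_to_reference <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  ref <- dataset$reference_gene
  if (!ref %in% rownames(dataset$mat)) {
    dataset$excluded <- TRUE
    return(dataset)
  }
  ref_value <- mean(dataset$mat[ref, ])
  if (ref_value == 0) {
    dataset$excluded <- TRUE
    return(dataset)
  }
  dataset$mat <- dataset$mat[setdiff(rownames(dataset$mat), ref), ,
                             drop = FALSE] / ref_value
  dataset$normalized <- TRUE
  dataset
}

#' Collapse normalised datasets by per-cell-type maximum
#'
#' Combines the non-excluded datasets into one gene x cell-type matrix,
#' taking for each (gene, cell type) the maximum normalised level over the
#' datasets containing it, without regard to stage. Genes absent from every
#' dataset are dropped. With an orthology map, genes without a one-to-one
#' mapping are dropped and the rows are renamed to the mapped identifiers.
#'
#' @param datasets List of normalised [expression_dataset()] objects.
#' @param orthology Optional tibble with columns `gene_id` and `ortholog`
#'   defining a one-to-one map; genes appearing more than once on either
#'   side are treated as lacking a high-quality mapping and dropped.
#' @return A gene x cell-type numeric matrix.
#' @export
collapse_max <- function(datasets, orthology = NULL) {
  datasets <- Filter(function(d) !d$excluded, datasets)
  if (length(datasets) == 0L) {
    stop_validation("no dataset survived reference-gene exclusion")
  }
  genes <- sort(unique(unlist(lapply(datasets, function(d)
    rownames(d$mat)))))
  cells <- sort(unique(unlist(lapply(datasets, function(d)
    colnames(d$mat)))))
  out <- matrix(-Inf, nrow = length(genes), ncol = length(cells),
                dimnames = list(genes, cells))
  seen <- matrix(FALSE, nrow = length(genes), ncol = length(cells))
  for (d in datasets) {
    ri <- match(rownames(d$mat), genes)
    ci <- match(colnames(d$mat), cells)
    out[ri, ci] <- pmax(out[ri, ci, drop = FALSE], d$mat)
    seen[ri, ci] <- TRUE
  }
  out[!seen] <- NA_real_

  if (!is.null(orthology)) {
    ok <- orthology |>
      dplyr::filter(!duplicated(.data$gene_id) &
                      !duplicated(.data$ortholog) &
                      !.data$gene_id %in%
                        .data$gene_id[duplicated(.data$gene_id)] &
                      !.data$ortholog %in%
                        .data$ortholog[duplicated(.data$ortholog)])
    keep <- intersect(rownames(out), ok$gene_id)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- ok$ortholog[match(keep, ok$gene_id)]
  }
  out
}

#' Piecewise logarithmic expression scaling
#'
#' Values below 1 are kept as-is; values at or above 1 are mapped to
#' 1 + log10(x). The map is continuous and monotone: levels between 1 and
#' 10 land in \[1, 2\], levels between 10 and 100 in \[2, 3\], and values
#' above 100 continue as 1 + log10(x) rather than being clamped.
#'
#' @param x Nonnegative numeric vector or matrix.
#' @return Scaled values of the same shape.
#' @examples
#' scale_levels(c(0.3, 1, 10, 100))  # 0.3, 1, 2, 3
#' @export
scale_levels <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop_validation("expression levels must be nonnegative")
  }
  out <- x
  hi <- !is.na(x) & x >= 1
  out[hi] <- 1 + log10(x[hi])
  out
}

#' Filter genes by expression variance across cell types
#'
#' Keeps genes whose variance across cell-type values strictly exceeds the
#' threshold, selecting genes with specific rather than uniform expression.
#' Population variance (divisor n) is the default convention.
#'
#' @param mat Scaled gene x cell-type matrix.
#' @param threshold Variance threshold (default 0.15).
#' @param convention `"population"` (default) or `"sample"`.
#' @return The subset matrix of high-variance genes.
#' @export
variance_filter <- function(mat, threshold = 0.15,
                            convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (ncol(mat) < 2L) stop_validation("need at least 2 cell types")
  v <- apply(mat, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(0)
    s2 <- var(x)
    if (convention == "population") s2 * (length(x) - 1) / length(x) else s2
  })
  mat[v > threshold, , drop = FALSE]
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of genes (rows) and, separately, cell types
#' (columns), with configurable distance and linkage. Rows are sorted by
#' gene id before clustering so the partition does not depend on input
#' order; cluster ids are relabelled in order of first appearance along
#' the sorted gene ids. Missing values are replaced by 0 (absent means not
#' observed above background) for distance computation.
#'
#' @param mat Scaled gene x cell-type matrix.
#' @param k Number of gene clusters to cut the dendrogram into.
#' @param distance Distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return An object of class `gene_clusters`: list with `clusters`
#'   (tibble `gene_id`, `cluster`), `gene_tree`, `cell_tree`, `k` and the
#'   matrix `mat` (rows in sorted order).
#' @export
cluster_genes <- function(mat, k, distance = "euclidean",
                          linkage = "complete") {
  if (nrow(mat) < 2L) stop_validation("need at least 2 genes to cluster")
  k <- check_count(k, "k")
  if (k > nrow(mat)) {
    stop_validation("k cannot exceed the number of genes")
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  filled <- mat
  filled[is.na(filled)] <- 0
  gene_tree <- hclust(dist(filled, method = distance), method = linkage)
  cell_tree <- if (ncol(mat) >= 2L) {
    hclust(dist(t(filled), method = distance), method = linkage)
  } else NULL
  raw <- cutree(gene_tree, k = k)
  relabel <- match(raw, unique(raw))
  structure(list(
    clusters = tibble::tibble(gene_id = rownames(mat), cluster = relabel),
    gene_tree = gene_tree, cell_tree = cell_tree, k = k, mat = mat),
    class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat(sprintf("<gene_clusters> %d genes in %d clusters over %d cell types\n",
              nrow(x$mat), x$k, ncol(x$mat)))
  invisible(x)
}

#' Band classification of a cluster expression profile
#'
#' Classifies mean scaled expression per cell-type group into bands: high
#' for means in (2, 3+\], middle for (1, 2\], low for \[0, 1\], and builds
#' a description listing groups by decreasing band (e.g. "high in HC, low
#' elsewhere").
#'
#' @param profile Named numeric vector: mean scaled expression per
#'   cell-type group.
#' @return A tibble with `group`, `mean_level`, `band`, plus attribute
#'   `description`.
#' @examples
#' classify_cluster(c(HC = 2.5, SC = 0.4, LW = 0.3))
#' @export
classify_cluster <- function(profile) {
  if (any(!is.finite(profile)) || any(profile < 0)) {
    stop_validation("cluster profile means must be finite and nonnegative")
  }
  band <- dplyr::case_when(profile > 2 ~ "high",
                           profile > 1 ~ "middle",
                           TRUE ~ "low")
  out <- tibble::tibble(group = names(profile), mean_level = profile,
                        band = factor(band,
                                      levels = c("high", "middle", "low")))
  present <- levels(out$band)[levels(out$band) %in% out$band]
  parts <- vapply(present, function(b) {
    sprintf("%s in %s", b,
            paste(out$group[out$band == b], collapse = ", "))
  }, character(1))
  if (length(parts) > 1L && sum(out$band == utils::tail(present, 1)) > 1L) {
    parts[length(parts)] <- sprintf("%s elsewhere",
                                    utils::tail(present, 1))
  }
  attr(out, "description") <- paste(parts, collapse = "; ")
  out
}

#' Describe every cluster of a clustering
#'
#' Averages scaled expression per cell-type group within each cluster and
#' applies [classify_cluster()].
#'
#' @param clustering A `gene_clusters` object from [cluster_genes()].
#' @param cell_groups Named character vector mapping cell types to groups
#'   (default [cochlear_cell_groups()]).
#' @return A tibble with one row per cluster x group: `cluster`, `group`,
#'   `mean_level`, `band`, `description` (one string per cluster),
#'   `n_genes`.
#' @export
describe_clusters <- function(clustering,
                              cell_groups = cochlear_cell_groups()) {
  stopifnot(inherits(clustering, "gene_clusters"))
  mat <- clustering$mat
  groups_of_cols <- cell_groups[colnames(mat)]
  if (anyNA(groups_of_cols)) {
    stop_validation("cell_groups must cover every cell type in the matrix")
  }
  purrr::map(sort(unique(clustering$clusters$cluster)), function(cl) {
    genes <- clustering$clusters$gene_id[clustering$clusters$cluster == cl]
    sub <- mat[genes, , drop = FALSE]
    profile <- vapply(split(seq_len(ncol(sub)), groups_of_cols),
                      function(ci) mean(sub[, ci], na.rm = TRUE),
                      numeric(1))
    profile[is.nan(profile)] <- 0
    cls <- classify_cluster(profile)
    dplyr::mutate(cls, cluster = cl,
                  description = attr(cls, "description"),
                  n_genes = length(genes), .before = 1L)
  }) |> dplyr::bind_rows()
}
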