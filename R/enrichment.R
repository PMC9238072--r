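#' Gene list set
#'
#' A universe of gene identifiers plus named subsets (curated lists).
#'
#' @param universe Character vector of gene ids.
#' @param lists Named list of character vectors, each a subset of
#'   `universe`.
#' @return An object of class `gene_list_set`.
#' @export
gene_list_set <- function(universe, lists = list()) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_validation("empty gene universe")
  if (length(lists) && is.null(names(lists))) {
    stop_validation("lists must be named")
  }
  lists <- lapply(lists, function(l) {
    l <- unique(as.character(l))
    outside <- setdiff(l, universe)
    if (length(outside)) {
      warn(sprintf("%d gene(s) outside the universe dropped from a list",
                   length(outside)))
    }
    intersect(l, universe)
  })
  structure(list(universe = universe, lists = lists),
            class = "gene_list_set")
}

#' @export
print.gene_list_set <- function(x, ...) {
  cat(sprintf("<gene_list_set> universe of %d genes; lists: %s\n",
              length(x$universe),
              paste(sprintf("%s (%d)", names(x$lists),
                            lengths(x$lists)), collapse = ", ")))
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' The probability of drawing at least `k` marked genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` are
#' marked: P(X >= k) for X ~ hypergeometric(N, K, n). The sum is carried
#' out in log space for numerical stability.
#'
#' @param N Universe size.
#' @param K Number of marked genes in the universe.
#' @param n Number of genes drawn (the query list size).
#' @param k Observed overlap.
#' @return A probability in (0, 1].
#' @examples
#' hypergeom_tail(10, 4, 5, 3)  # 66/252
#' hypergeom_tail(10, 4, 5, 0)  # exactly 1
#' @export
hypergeom_tail <- function(N, K, n, k) {
  for (v in c("N", "K", "n", "k")) {
    x <- get(v)
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 ||
        x != floor(x)) {
      stop_validation(sprintf("`%s` must be a single nonnegative integer", v))
    }
  }
  if (K > N || n > N) stop_validation("K and n cannot exceed N")
  if (k > min(K, n)) stop_validation("k cannot exceed min(K, n)")
  if (k == 0) return(1)
  i <- k:min(K, n)
  i <- i[n - i <= N - K]
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(logp)))
}

#' Hypergeometric enrichment of a query list against a reference list
#'
#' Intersects both lists with the universe, computes the upper-tail
#' hypergeometric probability of the observed overlap, and applies a
#' Bonferroni correction over `m` tests.
#'
#' @param query,reference Character vectors of gene ids.
#' @param universe Character vector or a [gene_list_set()].
#' @param m Number of tests the Bonferroni adjustment spans (default 1).
#' @return A one-row tibble: `N`, `K`, `n`, `k`, `p_raw`,
#'   `p_adj` (= min(1, m * p_raw)) and `m`.
#' @export
enrich <- function(query, reference, universe, m = 1L) {
  if (inherits(universe, "gene_list_set")) universe <- universe$universe
  if (length(universe) == 0L) stop_validation("empty gene universe")
  m <- check_count(m, "m")
  q_out <- setdiff(query, universe)
  r_out <- setdiff(reference, universe)
  if (length(q_out) || length(r_out)) {
    warn(sprintf(
      "dropped %d query and %d reference gene(s) absent from the universe",
      length(q_out), length(r_out)))
  }
  query <- intersect(unique(query), universe)
  reference <- intersect(unique(reference), universe)
  N <- length(unique(universe))
  K <- length(reference)
  n <- length(query)
  k <- length(intersect(query, reference))
  p_raw <- hypergeom_tail(N, K, n, k)
  tibble::tibble(N = N, K = K, n = n, k = k, p_raw = p_raw,
                 p_adj = min(1, m * p_raw), m = m)
}

#' Venn-region partition of two or three gene lists
#'
#' Partitions the union of the lists into disjoint regions (each region a
#' combination of list memberships) and reports counts and members,
#' optionally flagging members of a reference list.
#'
#' @param lists Named list of 2 or 3 character vectors.
#' @param reference Optional character vector (e.g. known deafness genes);
#'   flagged members are reported per region.
#' @return A tibble with one row per region: `region` (e.g. `"A&B"`),
#'   `n`, `genes` (list-column) and, when `reference` is given,
#'   `n_reference` and `reference_genes`.
#' @examples
#' overlap_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
overlap_partition <- function(lists, reference = NULL) {
  if (length(lists) < 2L || length(lists) > 3L) {
    stop_validation("overlap_partition supports 2 or 3 lists")
  }
  if (is.null(names(lists)) || any(names(lists) == "")) {
    stop_validation("lists must be named")
  }
  lists <- lapply(lists, unique)
  all_genes <- unique(unlist(lists))
  membership <- vapply(lists, function(l) all_genes %in% l,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(lists)))
  region <- unname(apply(membership, 1L, function(row) {
    paste(names(lists)[row], collapse = "&")
  }))
  out <- tibble::tibble(gene_id = all_genes, region = region) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(), genes = list(sort(.data$gene_id)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(stringr::str_count(.data$region, "&")),
                   .data$region)
  if (!is.null(reference)) {
    out <- out |>
      dplyr::mutate(
        reference_genes = purrr::map(.data$genes, intersect, reference),
        n_reference = lengths(.data$reference_genes))
  }
  out
}
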