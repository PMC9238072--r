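make_dataset <- function(mat, id = "ds1", stage = "P7", ref = "Hprt") {
  expression_dataset(id, stage, mat, ref)
}

test_that("reference normalisation divides by the reference level or excludes", {
  mat <- rbind(g1 = c(a = 5, b = 10), Hprt = c(a = 2, b = 2))
  norm <- normalize_to_reference(make_dataset(mat))
  expect_false(norm$excluded)
  expect_equal(norm$mat["g1", ], c(a = 2.5, b = 5))
  expect_false("Hprt" %in% rownames(norm$mat))

  # reference level 1: identity
  mat1 <- rbind(g1 = c(a = 5, b = 10), Hprt = c(a = 1, b = 1))
  expect_equal(normalize_to_reference(make_dataset(mat1))$mat["g1", ],
               mat1["g1", ])

  # reference 0 or absent: excluded, not an error
  mat0 <- rbind(g1 = c(a = 5, b = 10), Hprt = c(a = 0, b = 0))
  expect_true(normalize_to_reference(make_dataset(mat0))$excluded)
  matna <- rbind(g1 = c(a = 5, b = 10))
  expect_true(normalize_to_reference(make_dataset(matna))$excluded)
})

test_that("max-collapse keeps the per-cell-type maximum across datasets", {
  d1 <- make_dataset(rbind(g1 = c(a = 0.5, b = 1), Hprt = c(a = 1, b = 1)))
  d2 <- make_dataset(rbind(g1 = c(a = 2.0, b = 0.2),
                           g2 = c(a = 3, b = 4), Hprt = c(a = 1, b = 1)),
                     id = "ds2")
  collapsed <- collapse_max(list(normalize_to_reference(d1),
                                 normalize_to_reference(d2)))
  expect_equal(collapsed["g1", "a"], 2.0)
  expect_equal(collapsed["g1", "b"], 1)
  expect_equal(collapsed["g2", "a"], 3)

  # single dataset: identity
  single <- collapse_max(list(normalize_to_reference(d1)))
  expect_equal(single, normalize_to_reference(d1)$mat)
  # and collapsing an already-collapsed matrix is idempotent
  again <- collapse_max(list(make_dataset(rbind(single, Hprt = c(1, 1))) |>
                               normalize_to_reference()))
  expect_equal(again, single)

  # orthology: many-to-one genes are dropped, mapped names applied
  orth <- tibble::tibble(gene_id = c("g1", "g2", "g2"),
                         ortholog = c("M1", "M2", "M3"))
  mapped <- collapse_max(list(normalize_to_reference(d2)), orthology = orth)
  expect_equal(rownames(mapped), "M1")

  excluded <- normalize_to_reference(make_dataset(
    rbind(g1 = c(a = 1, b = 2), Hprt = c(a = 0, b = 0))))
  expect_error(collapse_max(list(excluded)),
               class = "hearload_validation_error")
})

test_that("piecewise log scaling is exact at its anchors and monotone", {
  expect_identical(scale_levels(1), 1)
  expect_equal(scale_levels(10), 2)
  expect_equal(scale_levels(100), 3)
  expect_identical(scale_levels(0.3), 0.3)
  expect_identical(scale_levels(0), 0)
  # the observed maximum of the normalised panels maps below 3
  expect_equal(scale_levels(70.6), 1 + log10(70.6), tolerance = 1e-12)
  expect_equal(scale_levels(70.6), 2.848805, tolerance = 1e-6)
  # values above 100 keep growing rather than clamping
  expect_gt(scale_levels(200), 3)

  grid <- seq(0, 150, length.out = 10000)
  scaled <- scale_levels(grid)
  expect_true(all(diff(scaled) >= 0))
  expect_error(scale_levels(-1), class = "hearload_validation_error")
})

test_that("variance filter keeps specifically expressed genes", {
  mat <- rbind(flat = c(1, 1, 1), spread = c(0, 3, 0),
               mild = c(1, 1.2, 1))
  kept <- variance_filter(mat, threshold = 0.15)
  expect_true("spread" %in% rownames(kept))
  expect_false("flat" %in% rownames(kept))
  expect_false("mild" %in% rownames(kept))

  # the stated conventions on a (0, 3) pair
  pair <- rbind(x = c(0, 3))
  expect_equal(nrow(variance_filter(pair, 2.0, "population")), 1)  # 2.25
  expect_equal(nrow(variance_filter(pair, 2.5, "population")), 0)
  expect_equal(nrow(variance_filter(pair, 4.0, "sample")), 1)      # 4.5
  # threshold zero keeps every non-constant row
  expect_equal(nrow(variance_filter(mat, 0)), 2)
})

test_that("clustering recovers planted blocks deterministically", {
  withr::local_seed(51)
  block1 <- matrix(rnorm(10 * 4, mean = 3, sd = 0.1), 10, 4)
  block2 <- matrix(rnorm(8 * 4, mean = 0, sd = 0.1), 8, 4)
  mat <- rbind(block1, block2)
  rownames(mat) <- sprintf("g%02d", 1:18)
  colnames(mat) <- sprintf("c%d", 1:4)
  cl <- cluster_genes(mat, k = 2)
  got <- cl$clusters$cluster
  expect_equal(dplyr::n_distinct(got[1:10]), 1)
  expect_equal(dplyr::n_distinct(got[11:18]), 1)
  expect_false(got[1] == got[11])

  # duplicate rows always co-cluster
  mat2 <- rbind(mat, g99 = mat["g01", ])
  cl2 <- cluster_genes(mat2, k = 2)
  expect_equal(cl2$clusters$cluster[cl2$clusters$gene_id == "g99"],
               cl2$clusters$cluster[cl2$clusters$gene_id == "g01"])

  # permuting the input rows leaves the partition unchanged
  perm <- sample(nrow(mat))
  cl_perm <- cluster_genes(mat[perm, ], k = 2)
  expect_identical(cl$clusters, cl_perm$clusters)

  expect_error(cluster_genes(mat, k = 50),
               class = "hearload_validation_error")
})

test_that("cluster band classification follows the level bands", {
  res <- classify_cluster(c(OHC = 2.5, SC = 0.4, LW = 0.3))
  expect_equal(as.character(res$band), c("high", "low", "low"))
  expect_match(attr(res, "description"), "high in OHC")
  expect_match(attr(res, "description"), "low elsewhere")

  res <- classify_cluster(c(A = 1.5, B = 1.5))
  expect_true(all(res$band == "middle"))
  # band boundaries: 2 is middle, 1 is low
  res <- classify_cluster(c(A = 2, B = 1, C = 2.0001))
  expect_equal(as.character(res$band), c("middle", "low", "high"))
  expect_error(classify_cluster(c(A = -0.1)),
               class = "hearload_validation_error")
})

test_that("synthetic marker panel clusters to its planted cell-type groups", {
  cfg <- sim_config(n_participants = 10, n_genes = 100, n_spiked = 2,
                    deafness_list_size = 10, variable_list_size = 10,
                    seed = 8)
  panel <- simulate_expression_panel(cfg)
  truth <- attr(panel, "marker_truth")
  norm <- lapply(panel, normalize_to_reference)
  collapsed <- collapse_max(norm)
  scaled <- scale_levels(collapsed)
  filtered <- variance_filter(scaled, 0.15)
  # markers survive the variance filter; background is mostly flat
  expect_true(all(truth$gene_id %in% rownames(filtered)))

  k <- dplyr::n_distinct(truth$home_group)
  cl <- cluster_genes(filtered[truth$gene_id, ], k = k)
  planted <- truth$home_group[match(cl$clusters$gene_id, truth$gene_id)]
  ari <- mclust::adjustedRandIndex(cl$clusters$cluster, planted)
  expect_gte(ari, 0.9)

  # each marker cluster is labelled with its home cell-type group
  desc <- describe_clusters(cl)
  for (cl_id in unique(cl$clusters$cluster)) {
    genes <- cl$clusters$gene_id[cl$clusters$cluster == cl_id]
    home <- unique(truth$home_group[truth$gene_id %in% genes])
    if (length(home) != 1L) next  # only pure clusters have one home
    top <- desc[desc$cluster == cl_id, ]
    expect_equal(top$group[which.max(top$mean_level)], home)
    expect_true(top$band[top$group == home] %in% c("high", "middle"))
  }
})
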