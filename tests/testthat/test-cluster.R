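# Enumerate all set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxlab) {
    k <- length(assign)
    if (k == n) { out[[length(out) + 1]] <<- assign; return(invisible()) }
    for (lab in seq_len(maxlab + 1))
      rec(c(assign, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# Weighted Newman modularity at a resolution parameter.
modularity_of <- function(W, labels, gamma = 1) {
  m2 <- sum(W)  # 2m for an undirected weight matrix with both triangles
  if (m2 == 0) return(0)
  deg <- rowSums(W)
  q <- 0
  for (lab in unique(labels)) {
    idx <- labels == lab
    q <- q + sum(W[idx, idx]) / m2 - gamma * (sum(deg[idx]) / m2)^2
  }
  q
}

test_that("SNN graph edges carry Jaccard weights of shared-neighbour sets", {
  # duplicated rows share identical kNN sets -> Jaccard 1
  set.seed(31)
  base <- matrix(rnorm(8 * 6), 8, 6)
  x <- rbind(base, base[1, ] + 1e-9)
  g <- build_snn_graph(x, k = 3)
  W <- igraph::as_adjacency_matrix(g$graph, attr = "weight", sparse = FALSE)
  expect_equal(W[1, 9], 1)
  expect_true(igraph::is_directed(g$graph) == FALSE)
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_true(all(W[W > 0] >= 1 / 15))
  expect_true(all(W <= 1))
})

test_that("SNN graph matches a brute-force construction with 1/15 pruning", {
  set.seed(32)
  x <- matrix(rnorm(40 * 10), 40, 10)
  k <- 6
  g <- build_snn_graph(x, k = k)
  D <- 1 - cor(t(x))
  knn <- t(apply(D, 1, function(r) order(r)[1:k]))
  W_ref <- matrix(0, 40, 40)
  for (i in 1:39) for (j in (i + 1):40) {
    inter <- length(intersect(knn[i, ], knn[j, ]))
    jac <- inter / (2 * k - inter)
    if (jac >= 1 / 15) W_ref[i, j] <- W_ref[j, i] <- jac
  }
  W <- igraph::as_adjacency_matrix(g$graph, attr = "weight", sparse = FALSE)
  expect_equal(unname(W), W_ref, tolerance = 1e-12)
  # a Jaccard of 1/16 (possible at k = 17 with overlap 2) is pruned
  expect_lt(1 / 16, 1 / 15)
})

test_that("constant vectors are excluded from the graph with a warning", {
  set.seed(33)
  x <- rbind(matrix(rnorm(30), 10, 3), c(2, 2, 2))
  expect_warning(g <- build_snn_graph(x, k = 3), "constant")
  expect_equal(igraph::vcount(g$graph), 10)
  labels <- louvain_cluster(g, resolution = 1)
  expect_equal(labels[11], -1L)
})

test_that("Louvain finds the max-modularity split of two cliques", {
  # two 4-cliques joined by one light edge; oracle = exhaustive search
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 0.25
  g <- igraph::graph_from_adjacency_matrix(W, "undirected", weighted = TRUE)
  got <- louvain_cluster(g, resolution = 1, seed = 1)
  parts <- all_partitions(8)
  qs <- vapply(parts, function(p) modularity_of(W, p), numeric(1))
  best <- parts[[which.max(qs)]]
  expect_equal(ari(got, best), 1)
  expect_equal(ari(got, c(1, 1, 1, 1, 2, 2, 2, 2)), 1)
})

test_that("Louvain is deterministic under a fixed seed and collapses at low resolution", {
  set.seed(34)
  x <- matrix(rnorm(60 * 8), 60, 8)
  g <- build_snn_graph(x, k = 10)
  l1 <- louvain_cluster(g, resolution = 0.5, seed = 7)
  l2 <- louvain_cluster(g, resolution = 0.5, seed = 7)
  expect_identical(l1, l2)
  K <- igraph::make_full_graph(10)
  igraph::E(K)$weight <- 1
  expect_equal(length(unique(louvain_cluster(K, resolution = 0.01))), 1L)
})

test_that("DBSCAN subclustering splits planted blobs and is inert otherwise", {
  set.seed(35)
  blob1 <- matrix(rnorm(30 * 10, 0, 0.05), 30, 10) +
    matrix(c(5, rep(0, 9)), 30, 10, byrow = TRUE)
  blob2 <- matrix(rnorm(30 * 10, 0, 0.05), 30, 10) +
    matrix(c(rep(0, 9), 5), 30, 10, byrow = TRUE)
  x <- rbind(blob1, blob2)
  labels <- rep(1L, 60)
  refined <- subcluster_dbscan(x, labels, eps = 0.2, min_samples = 5)
  expect_equal(length(unique(refined)), 2L)
  expect_equal(ari(refined, rep(1:2, each = 30)), 1)
  expect_equal(subcluster_dbscan(x, labels, eps = 10, min_samples = 5), labels)
  expect_equal(subcluster_dbscan(x, rep(-1L, 60), eps = 0.2), rep(-1L, 60))
})

test_that("medoid outlier removal flags anti-correlated members only", {
  base <- c(1, 2, 3, 4, 5)
  x <- rbind(matrix(rep(base, 6), 6, 5, byrow = TRUE) +
               matrix(rnorm(30, 0, 0.01), 6, 5),
             rev(base))
  labels <- rep(1L, 7)
  out <- remove_outliers(x, labels, min_corr = 0.6)
  expect_equal(out$outlier, c(rep(FALSE, 6), TRUE))
  none <- remove_outliers(x, labels, min_corr = -1)
  expect_false(any(none$outlier))
  same <- matrix(rep(base, 4), 4, 5, byrow = TRUE)
  expect_false(any(remove_outliers(same, rep(1L, 4), 0.6)$outlier))
})

test_that("cluster curation merges, removes and auto-merges correctly", {
  sim <- simulate_type_mixture(n = 300, K = 3, seed = 36)
  m <- fit_vst_model(sim$counts)
  res <- transform_vectors(m, sim$counts)
  sm <- structure(list(vectors = res, pixel_coords = cbind(seq_len(300), 1L),
                       genes = colnames(res), normalized = TRUE,
                       pixel_size_um = 1, bandwidth_um = 2.5, dim = 2L,
                       origin = c(0, 0)), class = "sample_matrix")
  cl <- cluster_vectors(sm, k = 15, resolution = 0.5, seed = 1)
  K <- ncol(cl$centroids$matrix)
  expect_gte(K, 3L)
  merged <- merge_clusters(cl, list(c(1L, 2L)))
  expect_equal(ncol(merged$centroids$matrix), K - 1L)
  idx <- which(cl$labels %in% c(1L, 2L))
  expect_true(all(merged$labels[idx] == merged$labels[idx][1]))
  removed <- remove_clusters(cl, 1L)
  expect_true(all(removed$labels[cl$labels == 1L] == -1L))
  expect_equal(ncol(removed$centroids$matrix), K - 1L)
  # distinct planted types never auto-merge at a 0.99 threshold
  auto <- auto_merge_clusters(cl, threshold = 0.99)
  expect_equal(ncol(auto$centroids$matrix), K)
})

test_that("centroids equal the mean of retained members exactly", {
  sim <- simulate_type_mixture(n = 200, K = 3, seed = 37)
  m <- fit_vst_model(sim$counts)
  res <- transform_vectors(m, sim$counts)
  sm <- structure(list(vectors = res, pixel_coords = cbind(seq_len(200), 1L),
                       genes = colnames(res), normalized = TRUE,
                       pixel_size_um = 1, bandwidth_um = 2.5, dim = 2L,
                       origin = c(0, 0)), class = "sample_matrix")
  cl <- cluster_vectors(sm, k = 15, resolution = 0.5, seed = 1)
  for (lab in sort(unique(cl$labels[cl$labels > 0]))) {
    keep <- cl$labels == lab & !cl$outlier_flags
    expect_equal(unname(cl$centroids$matrix[, paste0("C", lab)]),
                 unname(colMeans(res[keep, , drop = FALSE])))
  }
})

test_that("reference assignment maps centroids by max correlation over shared genes", {
  sig <- planted_signatures(12, 4)
  self <- assign_labels_to_reference(sig, sig)
  expect_equal(self$reference, sig$type_labels)
  expect_equal(self$r, rep(1, 4))
  shuffled <- signature_set(sig$matrix[, c(3, 1, 4, 2)])
  expect_equal(assign_labels_to_reference(sig, shuffled)$reference,
               sig$type_labels)
  set.seed(38)
  noisy <- signature_set(sig$matrix + matrix(rnorm(48, 0, 0.5), 12, 4),
                         sig$type_labels)
  withnoise <- assign_labels_to_reference(noisy, sig)
  expect_equal(withnoise$reference, sig$type_labels)
  expect_true(all(withnoise$r > 0.95))
  tiny <- signature_set(sig$matrix[1, , drop = FALSE])
  expect_error(assign_labels_to_reference(sig, tiny), "shared genes")
})

test_that("the clustering pipeline recovers planted mixtures exactly", {
  for (K in c(3, 5)) {
    sim <- simulate_type_mixture(n = 1000, K = K, seed = 40 + K)
    m <- fit_vst_model(sim$counts)
    res <- transform_vectors(m, sim$counts)
    sm <- structure(list(vectors = res,
                         pixel_coords = cbind(seq_len(1000), 1L),
                         genes = colnames(res), normalized = TRUE,
                         pixel_size_um = 1, bandwidth_um = 2.5, dim = 2L,
                         origin = c(0, 0)), class = "sample_matrix")
    cl <- cluster_vectors(sm, k = 15, resolution = 0.15, seed = 0)
    expect_equal(ncol(cl$centroids$matrix), K)
    expect_gt(ari(cl$labels, sim$type), 0.95)
  }
})

test_that("diagnostic bundles carry coordinates, profiles and embeddings", {
  sim <- simulate_type_mixture(n = 150, K = 3, seed = 44)
  m <- fit_vst_model(sim$counts)
  res <- transform_vectors(m, sim$counts)
  sm <- structure(list(vectors = res, pixel_coords = cbind(seq_len(150), 1L),
                       genes = colnames(res), normalized = TRUE,
                       pixel_size_um = 1, bandwidth_um = 2.5, dim = 2L,
                       origin = c(0, 0)), class = "sample_matrix")
  cl <- cluster_vectors(sm, k = 15, resolution = 0.5, seed = 1)
  ref <- signature_set(t(transform_vectors(m, t(sim$signatures))),
                       colnames(sim$signatures))
  bundles <- diagnostic_bundle(cl, reference = ref)
  expect_equal(length(bundles), ncol(cl$centroids$matrix))
  b1 <- bundles[[1]]
  expect_equal(ncol(b1$embedding), 2L)
  expect_equal(length(b1$mean_profile), 20L)
  expect_true(b1$best_reference %in% colnames(sim$signatures))
})
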