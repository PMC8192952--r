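# De novo cell-type signature discovery: shared-nearest-neighbour graph
# under correlation distance, Jaccard edge weights pruned at 1/15,
# Louvain community detection, optional DBSCAN subclustering, and
# medoid-based outlier curation.

#' Build the shared-nearest-neighbour graph of sampled vectors
#'
#' Neighbour lists are the `k` nearest vectors under correlation
#' distance (1 - Pearson r), each vector's own list including itself.
#' The edge weight between two vectors is the Jaccard similarity of
#' their neighbour sets; weights below 1/15 are set to zero and the
#' edge dropped. Vectors with zero variance (undefined correlation) are
#' excluded from the graph with a warning.
#'
#' @param x A normalized `sample_matrix` or a numeric n x genes matrix.
#' @param k Neighbour list size (default 30).
#' @return An `snn_graph`: the weighted [igraph::graph] plus the
#'   sample-index bookkeeping.
#' @export
build_snn_graph <- function(x, k = 30L) {
  mat <- if (inherits(x, "sample_matrix")) x$vectors else as.matrix(x)
  n_all <- nrow(mat)
  if (k >= n_all) stop("k must be smaller than the number of samples")
  sds <- apply(mat, 1, stats::sd)
  included <- which(sds > 0)
  if (length(included) < n_all)
    warning(sprintf("excluding %d constant vector(s) from the SNN graph",
                    n_all - length(included)))
  n <- length(included)
  if (k >= n) stop("k must be smaller than the number of usable samples")
  D <- 1 - stats::cor(t(mat[included, , drop = FALSE]))
  knn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(knn),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)  # |knn(i) o knn(j)| where sets overlap
  W <- methods::as(S, "TsparseMatrix")
  jac <- W@x / (2 * k - W@x)
  jac[jac < 1 / 15 - 1e-12] <- 0
  W@x <- jac
  W <- Matrix::drop0(W)
  Matrix::diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  structure(list(graph = g, included = included, n_samples = n_all,
                 knn = knn, k = k),
            class = "snn_graph")
}

#' Louvain community detection on an SNN graph
#'
#' @param snn An `snn_graph` (or a bare weighted igraph).
#' @param resolution Modularity resolution parameter (default 0.15).
#' @param seed RNG seed fixing the node processing order, making the
#'   partition deterministic.
#' @return Integer labels per original sample; samples excluded from
#'   the graph get `-1`.
#' @export
louvain_cluster <- function(snn, resolution = 0.15, seed = 0L) {
  g <- if (inherits(snn, "snn_graph")) snn$graph else snn
  if (igraph::vcount(g) == 0L) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- as.integer(igraph::membership(cl))
  if (inherits(snn, "snn_graph")) {
    labels <- rep(-1L, snn$n_samples)
    labels[snn$included] <- memb
    labels
  } else memb
}

# DBSCAN on a precomputed distance matrix. Returns 0 for noise.
dbscan_dist <- function(D, eps, min_samples) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' DBSCAN subclustering within each parent cluster
#'
#' Runs DBSCAN under correlation distance inside every Louvain cluster;
#' points flagged as noise keep the parent label, sub-clusters get new
#' labels scoped to their parent. Useful because Louvain is insensitive
#' to small clusters.
#'
#' @param x Normalized `sample_matrix` or matrix.
#' @param labels Integer parent labels (`-1` = unassigned, untouched).
#' @param eps DBSCAN radius in correlation distance.
#' @param min_samples Minimum neighbourhood size for a core point.
#' @return Refined integer labels, relabelled consecutively.
#' @export
subcluster_dbscan <- function(x, labels, eps, min_samples = 5L) {
  mat <- if (inherits(x, "sample_matrix")) x$vectors else as.matrix(x)
  out <- labels
  next_label <- max(labels, 0L)
  for (lab in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == lab)
    if (length(idx) < 2L) next
    D <- 1 - stats::cor(t(mat[idx, , drop = FALSE]))
    sub <- dbscan_dist(D, eps, min_samples)
    subs <- sort(unique(sub[sub > 0]))
    if (length(subs) <= 1L) next  # nothing split; noise keeps parent
    for (s in subs[-1]) {
      next_label <- next_label + 1L
      out[idx[sub == s]] <- next_label
    }
  }
  relabel_consecutive(out)
}

relabel_consecutive <- function(labels) {
  pos <- sort(unique(labels[labels > 0]))
  map <- match(labels, pos)
  out <- ifelse(is.na(map), -1L, map)
  as.integer(out)
}

#' Flag cluster members poorly correlated with their cluster medoid
#'
#' The medoid of a cluster is the member minimizing the summed
#' correlation distance to all members. Members whose Pearson
#' correlation to the medoid falls below `min_corr` are flagged as
#' outliers and excluded from centroid computation.
#'
#' @param x Normalized `sample_matrix` or matrix.
#' @param labels Integer cluster labels (`-1` ignored).
#' @param min_corr Minimum correlation to the medoid (default 0.6).
#' @return List with logical `outlier` flags and the `medoid` sample
#'   index per cluster.
#' @export
remove_outliers <- function(x, labels, min_corr = 0.6) {
  mat <- if (inherits(x, "sample_matrix")) x$vectors else as.matrix(x)
  outlier <- rep(FALSE, length(labels))
  medoids <- integer(0)
  for (lab in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == lab)
    if (length(idx) == 1L) {
      medoids[as.character(lab)] <- idx
      next
    }
    C <- suppressWarnings(stats::cor(t(mat[idx, , drop = FALSE])))
    C[!is.finite(C)] <- 0
    med <- which.max(colSums(C))
    medoids[as.character(lab)] <- idx[med]
    outlier[idx] <- C[, med] < min_corr
    if (all(outlier[idx])) outlier[idx[med]] <- FALSE  # keep the medoid
  }
  list(outlier = outlier, medoids = medoids)
}

cluster_centroids <- function(mat, labels, outlier, genes) {
  labs <- sort(unique(labels[labels > 0]))
  cen <- vapply(labs, function(lab) {
    idx <- which(labels == lab & !outlier)
    colMeans(mat[idx, , drop = FALSE])
  }, numeric(ncol(mat)))
  cen <- matrix(cen, nrow = ncol(mat),
                dimnames = list(genes, paste0("C", labs)))
  signature_set(cen, provenance = "de novo")
}

#' De novo clustering of normalized sampled vectors
#'
#' Orchestrates [build_snn_graph()], [louvain_cluster()], optional
#' [subcluster_dbscan()], and [remove_outliers()], and computes the
#' cluster centroids (cell-type signatures) from retained members.
#'
#' @param samples A normalized `sample_matrix`.
#' @param k SNN neighbour list size (default 30).
#' @param resolution Louvain resolution (default 0.15).
#' @param seed RNG seed for the Louvain node order.
#' @param dbscan_eps Optional DBSCAN radius enabling subclustering.
#' @param dbscan_min_samples DBSCAN core-point threshold.
#' @param min_corr_to_medoid Outlier cutoff (default 0.6).
#' @return A `cluster_result`: per-sample `labels` (`-1` = discarded),
#'   `centroids` (a [signature_set()]), `medoids`, `outlier_flags`, the
#'   member vectors and coordinates, and the parameters used.
#' @export
cluster_vectors <- function(samples, k = 30L, resolution = 0.15, seed = 0L,
                            dbscan_eps = NULL, dbscan_min_samples = 5L,
                            min_corr_to_medoid = 0.6) {
  if (!isTRUE(samples$normalized))
    warning("clustering unnormalized vectors; did you run normalize_samples()?")
  snn <- build_snn_graph(samples, k)
  labels <- louvain_cluster(snn, resolution, seed)
  if (!is.null(dbscan_eps))
    labels <- subcluster_dbscan(samples, labels, dbscan_eps,
                                dbscan_min_samples)
  out <- remove_outliers(samples, labels, min_corr_to_medoid)
  centroids <- cluster_centroids(samples$vectors, labels, out$outlier,
                                 samples$genes)
  structure(list(labels = labels, centroids = centroids,
                 medoids = out$medoids, outlier_flags = out$outlier,
                 vectors = samples$vectors,
                 pixel_coords = samples$pixel_coords,
                 genes = samples$genes,
                 params = list(k = k, resolution = resolution, seed = seed,
                               dbscan_eps = dbscan_eps,
                               dbscan_min_samples = dbscan_min_samples,
                               min_corr_to_medoid = min_corr_to_medoid)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- ncol(x$centroids$matrix)
  cat(sprintf("cluster_result: %d clusters over %d vectors (%d outliers, %d discarded)\n",
              k, length(x$labels), sum(x$outlier_flags),
              sum(x$labels == -1L)))
  invisible(x)
}

recompute_result <- function(result) {
  result$labels <- relabel_consecutive(result$labels)
  out <- remove_outliers(result$vectors, result$labels,
                         result$params$min_corr_to_medoid)
  result$medoids <- out$medoids
  result$outlier_flags <- out$outlier
  result$centroids <- cluster_centroids(result$vectors, result$labels,
                                        out$outlier, result$genes)
  result
}

#' Manually merge clusters
#'
#' @param result A `cluster_result`.
#' @param groups List of integer vectors; the clusters in each vector
#'   are merged (members unioned, centroid recomputed).
#' @return The curated `cluster_result`, relabelled consecutively.
#' @export
merge_clusters <- function(result, groups) {
  labels <- result$labels
  for (grp in groups) {
    grp <- as.integer(grp)
    labels[labels %in% grp] <- min(grp)
  }
  result$labels <- labels
  recompute_result(result)
}

#' Remove (discard) clusters
#'
#' @param result A `cluster_result`.
#' @param labels Integer cluster labels to discard; members get `-1`.
#' @return The curated `cluster_result`, relabelled consecutively.
#' @export
remove_clusters <- function(result, labels) {
  result$labels[result$labels %in% as.integer(labels)] <- -1L
  recompute_result(result)
}

#' Automatically merge clusters with near-identical centroids
#'
#' Iteratively merges the pair of clusters with the highest centroid
#' Pearson correlation above `threshold`, recomputing centroids after
#' each merge.
#'
#' @param result A `cluster_result`.
#' @param threshold Centroid correlation above which a pair merges.
#' @return The curated `cluster_result`.
#' @export
auto_merge_clusters <- function(result, threshold = 0.9) {
  repeat {
    cen <- result$centroids$matrix
    if (ncol(cen) < 2L) return(result)
    C <- stats::cor(cen)
    C[lower.tri(C, diag = TRUE)] <- -Inf
    if (max(C) <= threshold) return(result)
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    labs <- as.integer(sub("^C", "", colnames(cen)[ij]))
    result <- merge_clusters(result, list(labs))
  }
}

#' Map de novo centroids to the closest reference signatures
#'
#' Each centroid is assigned the reference type with maximal Pearson
#' correlation over the shared genes (alignment by gene name;
#' many-to-one mappings allowed).
#'
#' @param centroids A [signature_set()] (e.g. `result$centroids`).
#' @param reference A [signature_set()] of reference types.
#' @return Data frame with `cluster`, the best `reference` type, and
#'   the achieved correlation `r`.
#' @export
assign_labels_to_reference <- function(centroids, reference) {
  shared <- intersect(rownames(centroids$matrix), rownames(reference$matrix))
  if (length(shared) < 2L) stop("fewer than 2 shared genes with the reference")
  A <- centroids$matrix[shared, , drop = FALSE]
  B <- reference$matrix[shared, , drop = FALSE]
  C <- stats::cor(A, B)
  best <- max.col(C, ties.method = "first")
  data.frame(cluster = colnames(A),
             reference = colnames(B)[best],
             r = C[cbind(seq_len(nrow(C)), best)],
             stringsAsFactors = FALSE)
}

#' Assemble per-cluster diagnostic data
#'
#' For each cluster, collects (1) member pixel coordinates, (2) the
#' pixels classified to the cluster's centroid in a cell-type map,
#' (3) the mean expression profile with the best-correlating reference
#' signature if available, and (4) a 2D embedding (principal
#' components) of the member vectors. Data only; rendering is left to
#' the caller.
#'
#' @param result A `cluster_result`.
#' @param ctmap Optional `cell_type_map` produced from `result`.
#' @param reference Optional reference [signature_set()].
#' @return Named list, one entry per cluster.
#' @export
diagnostic_bundle <- function(result, ctmap = NULL, reference = NULL) {
  members <- which(result$labels > 0)
  emb <- stats::prcomp(result$vectors[members, , drop = FALSE],
                       rank. = 2L)$x
  ref_match <- if (!is.null(reference))
    assign_labels_to_reference(result$centroids, reference) else NULL
  labs <- sort(unique(result$labels[result$labels > 0]))
  out <- lapply(labs, function(lab) {
    idx <- which(result$labels == lab)
    bundle <- list(
      member_coords = result$pixel_coords[idx, , drop = FALSE],
      mean_profile = colMeans(result$vectors[idx, , drop = FALSE]),
      embedding = emb[match(idx, members), , drop = FALSE])
    if (!is.null(ctmap))
      bundle$classified_coords <-
        coords_from_index(which(ctmap$labels$labels == lab),
                          dim(ctmap$labels$labels))
    if (!is.null(ref_match)) {
      row <- ref_match[ref_match$cluster == paste0("C", lab), ]
      bundle$best_reference <- row$reference
      bundle$best_reference_r <- row$r
    }
    bundle
  })
  names(out) <- paste0("C", labs)
  out
}
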