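# Shared fixture builders and independent brute-force oracles.

# Wrap a dense array (spatial dims x genes) as a vector_field object.
make_field <- function(values, genes = NULL, pixel_size = 1, h = 2.5,
                       origin = NULL, normalized = FALSE) {
  d <- length(dim(values)) - 1L
  shape <- dim(values)[seq_len(d)]
  genes <- genes %||% sprintf("g%02d", seq_len(dim(values)[d + 1L]))
  structure(list(values = values, genes = genes, pixel_size_um = pixel_size,
                 bandwidth_um = h, dim = d, origin = origin %||% rep(0, d),
                 shape = shape, normalized = normalized),
            class = "vector_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force local maxima: window^d neighbourhood max with clamped
# (edge-replicating) boundary, computed pixel by pixel.
bf_local_maxima <- function(r, window = 3L) {
  w2 <- (window - 1L) %/% 2L
  shape <- dim(r)
  d <- length(shape)
  hits <- NULL
  idx <- as.matrix(expand.grid(lapply(shape, seq_len)))
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (r[matrix(p, 1)] <= 0) next
    rng <- lapply(seq_len(d), function(a)
      pmin(pmax((p[a] - w2):(p[a] + w2), 1L), shape[a]))
    neigh <- do.call(`[`, c(list(r), rng))
    if (r[matrix(p, 1)] >= max(neigh)) hits <- rbind(hits, p)
  }
  if (is.null(hits)) matrix(integer(0), 0, d) else unname(hits)
}

# Brute-force pixel classification by per-pixel stats::cor.
bf_classify <- function(field, prototypes, min_corr, exclude = NULL) {
  mat <- matrix(field$values, nrow = prod(field$shape),
                dimnames = list(NULL, field$genes))
  P <- prototypes$matrix[field$genes, , drop = FALSE]
  out <- rep(-1L, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    if (all(v == 0)) next
    if (!is.null(exclude) && exclude[i]) next
    if (stats::sd(v) == 0) next
    rs <- apply(P, 2, function(p) suppressWarnings(stats::cor(v, p)))
    rs[is.na(rs)] <- -Inf
    if (max(rs) >= min_corr) out[i] <- which.max(rs)
  }
  array(out, field$shape)
}

# Brute-force nearest retained window centre per pixel.
bf_voronoi <- function(window_labels, centers, shape, radius_px) {
  idx <- as.matrix(expand.grid(lapply(shape, seq_len)))
  out <- rep(-1L, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    d2 <- rowSums(sweep(centers, 2, idx[i, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= radius_px) out[i] <- window_labels[j]
  }
  array(out, shape)
}

# Minimal cell_type_map around a label array, for domain/evaluate tests.
make_ctmap <- function(labels, label_names, pixel_size = 1) {
  list(labels = label_raster(labels, label_names, pixel_size),
       max_corr = array(NA_real_, dim(labels)),
       prototypes = NULL, min_corr_threshold = 0) |>
    structure(class = "cell_type_map")
}

# Simulate an n x G matrix of NB counts with planted slope against a
# latent log10 depth; returns counts plus the latent totals.
simulate_nb_samples <- function(n, G, theta, b1 = 1, seed = 1) {
  set.seed(seed)
  m <- 10^stats::runif(n, 1.5, 3)
  b0 <- stats::runif(G, -1, 1)
  mu <- exp(outer(log10(m), rep(b1, G)) + matrix(b0, n, G, byrow = TRUE))
  y <- matrix(stats::rnbinom(n * G, mu = mu, size = theta), n, G)
  colnames(y) <- sprintf("g%02d", seq_len(G))
  list(counts = y, totals = m, b0 = b0, b1 = b1, theta = theta)
}

# Mixture of K planted NB expression profiles (cluster-recovery tests).
simulate_type_mixture <- function(n, K, G = 20, mean_high = 25,
                                  theta = 10, seed = 1) {
  set.seed(seed)
  sig <- planted_signatures(G, K, mean_high = mean_high)$matrix
  type <- sample.int(K, n, replace = TRUE)
  y <- t(vapply(type, function(t)
    stats::rnbinom(G, mu = sig[, t], size = theta), numeric(G)))
  colnames(y) <- rownames(sig)
  list(counts = y, type = type, signatures = sig)
}

# Otsu's threshold, used by the naive intensity-threshold segmentation
# baseline in the low-expression sensitivity check.
otsu_threshold <- function(v, nbins = 256) {
  h <- hist(v, breaks = seq(min(v), max(v), length.out = nbins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  w1 <- cumsum(p); mu <- cumsum(p * h$mids); muT <- mu[length(mu)]
  sb <- (muT * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  h$mids[which.max(sb)]
}

# Adjusted Rand index (independent of the pipeline code path).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_same_coords <- function(a, b) {
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(a), key(b))
}
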