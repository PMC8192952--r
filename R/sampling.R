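# Downsampling of the vector field to representative expression vectors:
# local-maxima selection on the L1 raster (default) or random sampling,
# followed by expression thresholds and an optional kNN density filter.

# Separable maximum filter with edge-replicating (reflect) boundary.
max_filter <- function(r, window = 3L) {
  if (window %% 2L != 1L || window < 3L) stop("window must be odd and >= 3")
  w2 <- (window - 1L) %/% 2L
  d <- length(dim(r))
  out <- r
  for (axis in seq_len(d)) {
    n <- dim(out)[axis]
    acc <- out  # freeze this axis' input: shifts must not compound
    for (o in seq(-w2, w2)) {
      if (o == 0L) next
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- switch(paste0(d, ".", axis),
        "2.1" = acc[idx, , drop = FALSE],
        "2.2" = acc[, idx, drop = FALSE],
        "3.1" = acc[idx, , , drop = FALSE],
        "3.2" = acc[, idx, , drop = FALSE],
        "3.3" = acc[, , idx, drop = FALSE])
      out <- pmax(out, shifted)
    }
  }
  out
}

#' Find local maxima of a scalar raster
#'
#' A pixel is a local maximum when the size-`window` maximum filter of
#' the raster equals the raster at that pixel; plateau pixels all
#' qualify, zero-valued pixels never do. The filter replicates edge
#' values at the boundary so no spurious edge maxima arise.
#'
#' @param raster Numeric 2D or 3D array (typically the L1 norm of a raw
#'   vector field, see [field_l1_norm()]).
#' @param window Odd filter size, default 3.
#' @return Integer matrix of pixel coordinates, one row per maximum.
#' @export
find_local_maxima <- function(raster, window = 3L) {
  raster <- as.array(raster)
  filt <- max_filter(raster, window)
  hits <- which(filt == raster & raster > 0)
  coords_from_index(hits, dim(raster))
}

coords_from_index <- function(idx, shape) {
  d <- length(shape)
  out <- matrix(0L, length(idx), d)
  rem <- idx - 1L
  for (a in seq_len(d)) {
    out[, a] <- as.integer(rem %% shape[a]) + 1L
    rem <- rem %/% shape[a]
  }
  colnames(out) <- c("x", "y", "z")[seq_len(d)]
  out
}

#' Filter pixel coordinates by expression thresholds
#'
#' Keeps coordinates whose pixel vector has (a) a maximum single-gene
#' value of at least `gene_threshold` and (b) an L1 norm of at least
#' `l1_threshold`. A per-gene threshold of one kernel height (see
#' [kernel_height()]) discards locations carrying only Gaussian-tail
#' signal.
#'
#' @param field A raw `vector_field`.
#' @param coords Integer pixel coordinate matrix (rows).
#' @param gene_threshold Minimum single-gene expression (>= 0).
#' @param l1_threshold Minimum total (L1) expression (>= 0).
#' @return The subset of `coords` passing both thresholds.
#' @export
apply_expression_thresholds <- function(field, coords, gene_threshold = 0,
                                        l1_threshold = 0) {
  if (gene_threshold < 0 || l1_threshold < 0) stop("thresholds must be >= 0")
  if (nrow(coords) == 0L) return(coords)
  vec <- field_vectors_at(field, coords)
  keep <- apply(vec, 1, max) >= gene_threshold & rowSums(vec) >= l1_threshold
  coords[keep, , drop = FALSE]
}

# k-th nearest-neighbour distance (to other points), chunked.
knn_distance <- function(coords, k, chunk = 1024L) {
  n <- nrow(coords)
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of points (%d)", k, n))
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    D <- cross_dist(coords[rows, , drop = FALSE], coords)
    D[cbind(seq_along(rows), rows)] <- Inf
    out[rows] <- apply(D, 1, function(v) sort(v, partial = k)[k])
  }
  out
}

#' Critical radius of the kNN density filter
#'
#' The distance at which a point's kNN-estimated local density equals
#' the threshold: points whose k-th neighbour lies farther than this
#' radius are removed. For k = 100 and threshold 0.002 per square
#' micrometre in 2D this is about 126.2 micrometres.
#'
#' @param k Neighbour count.
#' @param density_threshold Minimum local density (per micrometre^d).
#' @param d Spatial dimension, 2 or 3.
#' @return Radius in micrometres.
#' @export
critical_knn_radius <- function(k, density_threshold, d = 2) {
  (k / (density_threshold * unit_ball_coef(d)))^(1 / d)
}

#' kNN local-density filter for sampled locations
#'
#' Estimates the local density at each point as
#' `k / (V_d * r_k^d)` with `r_k` the distance to its k-th nearest other
#' point and `V_d` the unit-ball volume coefficient (`pi` in 2D,
#' `4*pi/3` in 3D), and removes points whose density falls below
#' `density_threshold`. Used to discard sparse spurious maxima outside
#' the tissue area.
#'
#' @param coords_um Numeric matrix of point positions in micrometres.
#' @param k Neighbour count (must be `< nrow(coords_um)`).
#' @param density_threshold Minimum density (per micrometre^d).
#' @param d Spatial dimension (default: `ncol(coords_um)`).
#' @return Logical vector, `TRUE` for points kept.
#' @export
knn_density_filter <- function(coords_um, k, density_threshold,
                               d = ncol(coords_um)) {
  coords_um <- as.matrix(coords_um)
  if (density_threshold <= 0) return(rep(TRUE, nrow(coords_um)))
  rk <- knn_distance(coords_um, k)
  density <- k / (unit_ball_coef(d) * rk^d)
  density >= density_threshold
}

#' Extract pixel vectors at given coordinates
#'
#' @param field A `vector_field`.
#' @param coords Integer pixel coordinate matrix; order is preserved.
#' @param method Provenance tag for the sample set.
#' @return A `sample_matrix`: sampled vectors with their pixel
#'   coordinates and the field metadata needed downstream.
#' @export
extract_vectors <- function(field, coords, method = "manual") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  vectors <- if (nrow(coords)) field_vectors_at(field, coords) else
    matrix(0, 0, length(field$genes), dimnames = list(NULL, field$genes))
  structure(list(vectors = vectors, pixel_coords = coords, method = method,
                 genes = field$genes, pixel_size_um = field$pixel_size_um,
                 bandwidth_um = field$bandwidth_um, dim = field$dim,
                 origin = field$origin, normalized = isTRUE(field$normalized),
                 filter_flags = NULL),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("sample_matrix: %d vectors x %d genes (%s%s)\n",
              nrow(x$vectors), ncol(x$vectors), x$method,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Randomly sample eligible pixel vectors
#'
#' Uniform sampling without replacement among pixels that pass the same
#' expression thresholds used for local-maxima selection.
#'
#' @param field A raw `vector_field`.
#' @param n Number of vectors to draw.
#' @param gene_threshold,l1_threshold Expression thresholds (see
#'   [apply_expression_thresholds()]).
#' @param seed Optional RNG seed for reproducibility.
#' @return A `sample_matrix` with `method = "random"`.
#' @export
random_sample_vectors <- function(field, n, gene_threshold = 0,
                                  l1_threshold = 0, seed = NULL) {
  mat <- field_matrix(field)
  eligible <- which(apply(mat, 1, max) >= gene_threshold &
                      rowSums(mat) >= l1_threshold & rowSums(mat) > 0)
  if (length(eligible) < n)
    stop(sprintf("only %d eligible pixels for a sample of %d",
                 length(eligible), n))
  if (!is.null(seed)) set.seed(seed)
  picked <- if (length(eligible) == n) eligible else
    sample(eligible, n, replace = FALSE)
  extract_vectors(field, coords_from_index(picked, field$shape),
                  method = "random")
}

#' Downsample a vector field to representative vectors
#'
#' The default strategy selects local maxima of the L1-norm raster of
#' the raw field, applies the per-gene and L1 expression thresholds,
#' and optionally removes sparse maxima with the kNN density filter.
#' `method = "random"` instead draws the same kind of sample uniformly
#' among threshold-passing pixels.
#'
#' @param field A raw `vector_field`.
#' @param method `"local_maxima"` (default) or `"random"`.
#' @param window Maximum-filter size for local maxima detection.
#' @param gene_threshold,l1_threshold Expression thresholds.
#' @param knn_k,knn_density_threshold kNN density filter parameters;
#'   filter disabled when either is `NULL`.
#' @param n Sample size (`"random"` method only).
#' @param seed RNG seed (`"random"` method only).
#' @return A `sample_matrix` whose `filter_flags` records, for every
#'   candidate location, which filters it passed.
#' @export
sample_vectors <- function(field, method = c("local_maxima", "random"),
                           window = 3L, gene_threshold = 0, l1_threshold = 0,
                           knn_k = NULL, knn_density_threshold = NULL,
                           n = NULL, seed = NULL) {
  method <- match.arg(method)
  if (method == "random") {
    if (is.null(n)) stop("random sampling needs a sample size n")
    return(random_sample_vectors(field, n, gene_threshold, l1_threshold, seed))
  }
  cand <- find_local_maxima(field_l1_norm(field), window)
  vec <- field_vectors_at(field, cand)
  pass_gene <- apply(vec, 1, max) >= gene_threshold
  pass_l1 <- rowSums(vec) >= l1_threshold
  keep <- pass_gene & pass_l1
  pass_density <- rep(NA, nrow(cand))
  if (!is.null(knn_k) && !is.null(knn_density_threshold) && any(keep)) {
    kept_idx <- which(keep)
    coords_um <- sweep(sweep((cand[kept_idx, , drop = FALSE] - 0.5), 2,
                             rep(field$pixel_size_um, field$dim), "*"),
                       2, field$origin, "+")
    ok <- knn_density_filter(coords_um, knn_k, knn_density_threshold,
                             d = field$dim)
    pass_density[kept_idx] <- ok
    keep[kept_idx] <- ok
  }
  out <- extract_vectors(field, cand[keep, , drop = FALSE],
                         method = "local_maxima")
  out$filter_flags <- data.frame(cand, passed_gene_threshold = pass_gene,
                                 passed_l1_threshold = pass_l1,
                                 passed_density_filter = pass_density,
                                 kept = keep)
  out
}
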