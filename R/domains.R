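# Tissue-domain segmentation: local cell-type composition in a sliding
# circular (2D) or spherical (3D) window, agglomerative clustering of
# window compositions, correlation-based merging, and nearest-centre
# rasterization back to full field resolution.

# Integer offsets of pixels whose centres lie within radius_px of a
# window centre pixel, as an n x d matrix.
disc_offsets <- function(radius_px, d) {
  r <- ceiling(radius_px)
  ax <- lapply(seq_len(d), function(a) seq(-r, r))
  off <- as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
  off[rowSums(off^2) <= radius_px^2, , drop = FALSE]
}

#' Cell-type composition in a sliding window
#'
#' Window centres lie on a `step_um` grid over the map; each window
#' counts the cell-type labels of the pixels whose centres fall within
#' `radius_um` (unclassified pixels excluded) and normalizes the counts
#' to proportions. Windows with fewer classified pixels than
#' `min_classified_frac` of the window's pixel count are dropped.
#'
#' @param ctmap A `cell_type_map`.
#' @param radius_um Window radius in micrometres (circular in 2D,
#'   spherical in 3D).
#' @param step_um Sliding step in micrometres.
#' @param min_classified_frac Minimum fraction of in-window pixels that
#'   must be classified for the window to be retained (default 0.01).
#' @return List with `centers` (pixel coordinates of retained windows),
#'   `compositions` (windows x types matrix, rows summing to 1),
#'   `all_centers` and `retained` bookkeeping, and the window geometry.
#' @export
window_composition <- function(ctmap, radius_um = 100, step_um = 10,
                               min_classified_frac = 0.01) {
  px <- ctmap$labels$pixel_size_um
  if (radius_um < px) stop("window radius must be at least one pixel")
  labels <- ctmap$labels$labels
  shape <- dim(labels)
  d <- length(shape)
  K <- length(ctmap$labels$label_names)
  step_px <- max(1L, round(step_um / px))
  radius_px <- radius_um / px
  centers <- as.matrix(expand.grid(lapply(shape, function(n)
    seq(1L, n, by = step_px)), KEEP.OUT.ATTRS = FALSE))
  colnames(centers) <- c("x", "y", "z")[seq_len(d)]
  off <- disc_offsets(radius_px, d)
  min_count <- max(1, ceiling(min_classified_frac * nrow(off)))
  comp <- matrix(0, nrow(centers), K,
                 dimnames = list(NULL, ctmap$labels$label_names))
  counts <- integer(nrow(centers))
  for (w in seq_len(nrow(centers))) {
    pix <- sweep(off, 2, centers[w, ], "+")
    inside <- rep(TRUE, nrow(pix))
    for (a in seq_len(d)) inside <- inside & pix[, a] >= 1L & pix[, a] <= shape[a]
    lab <- labels[grid_index(pix[inside, , drop = FALSE], shape)]
    lab <- lab[lab > 0]
    counts[w] <- length(lab)
    if (length(lab)) comp[w, ] <- tabulate(lab, K) / length(lab)
  }
  retained <- counts >= min_count
  if (!any(retained)) warning("no window retained; is the map classified?")
  list(centers = centers[retained, , drop = FALSE],
       compositions = comp[retained, , drop = FALSE],
       all_centers = centers, retained = retained,
       radius_px = radius_px, step_px = step_px, shape = shape)
}

#' Agglomerative clustering of window compositions
#'
#' Hierarchical clustering (Euclidean distance, average linkage by
#' default) of the window composition vectors, cut at `n_initial`
#' clusters.
#'
#' @param compositions Windows x types proportion matrix.
#' @param n_initial Number of initial clusters to cut.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return Integer window labels in `1..n_initial`.
#' @export
cluster_compositions <- function(compositions, n_initial = 15,
                                 linkage = "average") {
  n_initial <- min(n_initial, nrow(compositions))
  hc <- stats::hclust(stats::dist(compositions), method = linkage)
  as.integer(stats::cutree(hc, k = n_initial))
}

domain_means <- function(labels, compositions) {
  labs <- sort(unique(labels))
  m <- vapply(labs, function(l)
    colMeans(compositions[labels == l, , drop = FALSE]),
    numeric(ncol(compositions)))
  matrix(m, ncol = length(labs),
         dimnames = list(colnames(compositions), labs))
}

# Label pairs touching along a 4-neighbourhood (2D) / 6-neighbourhood
# (3D) boundary in a label raster (-1 ignored).
adjacent_label_pairs <- function(raster) {
  d <- length(dim(raster))
  pairs <- NULL
  for (axis in seq_len(d)) {
    n <- dim(raster)[axis]
    if (n < 2L) next
    idx_a <- lapply(dim(raster), seq_len); idx_b <- idx_a
    idx_a[[axis]] <- 1:(n - 1); idx_b[[axis]] <- 2:n
    a <- do.call(`[`, c(list(raster), idx_a))
    b <- do.call(`[`, c(list(raster), idx_b))
    sel <- a != b & a != -1L & b != -1L
    if (any(sel))
      pairs <- rbind(pairs, unique(cbind(pmin(a[sel], b[sel]),
                                         pmax(a[sel], b[sel]))))
  }
  if (is.null(pairs)) matrix(integer(0), 0, 2) else unique(pairs)
}

#' Merge window clusters into tissue domains
#'
#' Two-phase merging: first, any pair of clusters whose mean
#' compositions have Pearson correlation above `corr_threshold` is
#' merged (highest-correlation pair first, means recomputed after every
#' merge); second, pairs that are spatially adjacent in the draft
#' domain map and correlate above `adjacency_corr_threshold` are merged
#' the same way. Phase 2 is skipped when `adjacency_corr_threshold` is
#' `NULL`.
#'
#' @param labels Integer window labels.
#' @param compositions Windows x types proportion matrix.
#' @param corr_threshold Phase-1 correlation threshold (default 0.8).
#' @param adjacency_corr_threshold Phase-2 threshold (default 0.6).
#' @param geometry Window geometry as returned by
#'   [window_composition()] (needed for phase 2 rasterization).
#' @return Integer window labels relabelled to `1..D`.
#' @export
merge_domains <- function(labels, compositions, corr_threshold = 0.8,
                          adjacency_corr_threshold = 0.6, geometry = NULL) {
  labels <- as.integer(labels)
  merge_pass <- function(labels, adjacency = NULL) {
    repeat {
      labs <- sort(unique(labels))
      if (length(labs) < 2L) return(labels)
      M <- domain_means(labels, compositions)
      C <- suppressWarnings(stats::cor(M))
      C[!is.finite(C)] <- -Inf
      C[lower.tri(C, diag = TRUE)] <- -Inf
      thr <- if (is.null(adjacency)) corr_threshold else
        adjacency_corr_threshold
      if (!is.null(adjacency)) {
        allowed <- matrix(FALSE, length(labs), length(labs))
        adj <- adjacency()
        for (r in seq_len(nrow(adj))) {
          i <- match(adj[r, 1], labs); j <- match(adj[r, 2], labs)
          if (!is.na(i) && !is.na(j)) allowed[min(i, j), max(i, j)] <- TRUE
        }
        C[!allowed] <- -Inf
      }
      if (max(C) <= thr) return(labels)
      ij <- which(C == max(C), arr.ind = TRUE)[1, ]
      labels[labels == labs[ij[2]]] <- labs[ij[1]]
    }
  }
  labels <- merge_pass(labels)
  if (!is.null(adjacency_corr_threshold)) {
    if (is.null(geometry))
      stop("adjacency merging needs the window geometry")
    adjacency <- function() {
      draft <- rasterize_domains(labels, geometry)
      adjacent_label_pairs(draft$labels)
    }
    labels <- merge_pass(labels, adjacency)
  }
  match(labels, sort(unique(labels)))
}

#' Rasterize window labels to full map resolution
#'
#' Every pixel takes the label of its nearest retained window centre
#' (nearest-neighbour upsampling of the step-grid label image); pixels
#' farther than the window radius from every retained centre stay
#' unclassified.
#'
#' @param window_labels Integer labels of the retained windows.
#' @param geometry Window geometry from [window_composition()].
#' @param pixel_size_um Pixel size stored on the output raster.
#' @param origin Grid origin stored on the output raster.
#' @return A [label_raster()] of domain labels.
#' @export
rasterize_domains <- function(window_labels, geometry, pixel_size_um = 1,
                              origin = NULL) {
  shape <- geometry$shape
  d <- length(shape)
  step <- geometry$step_px
  ngrid <- vapply(shape, function(n) length(seq(1L, n, by = step)), 1L)
  lab_all <- rep(NA_integer_, nrow(geometry$all_centers))
  lab_all[geometry$retained] <- as.integer(window_labels)
  npix <- prod(shape)
  pix <- coords_from_index(seq_len(npix), shape)
  # nearest centre lies among the <=2^d surrounding grid centres; track
  # the (distance, centre index) minimum with first-index tie-break to
  # match a brute-force argmin over centres in grid order
  lo <- sapply(seq_len(d), function(a)
    pmin(pmax((pix[, a] - 1L) %/% step + 1L, 1L), ngrid[a]))
  lo <- matrix(lo, ncol = d)
  best_d2 <- rep(Inf, npix); best_idx <- rep(NA_integer_, npix)
  for (mask in 0:(2^d - 1)) {
    ci <- lo
    for (a in seq_len(d)) if (bitwAnd(mask, 2^(a - 1)))
      ci[, a] <- pmin(ci[, a] + 1L, ngrid[a])
    cpos <- (ci - 1L) * step + 1L
    d2 <- rowSums((pix - cpos)^2)
    idx <- grid_index(ci, ngrid)
    take <- d2 < best_d2 | (d2 == best_d2 & idx < best_idx)
    take[is.na(take)] <- TRUE
    best_d2[take] <- d2[take]; best_idx[take] <- idx[take]
  }
  out <- lab_all[best_idx]
  dist_near <- sqrt(best_d2)
  # pixels whose globally nearest centre was dropped: exact search over
  # the retained centres
  fb <- which(is.na(out))
  if (length(fb)) {
    centers <- geometry$centers
    for (start in seq(1L, length(fb), by = 4096L)) {
      rows <- fb[start:min(start + 4095L, length(fb))]
      Dm <- cross_dist(pix[rows, , drop = FALSE], centers)
      nearest <- max.col(-Dm, ties.method = "first")
      out[rows] <- window_labels[nearest]
      dist_near[rows] <- Dm[cbind(seq_along(rows), nearest)]
    }
  }
  out[dist_near > geometry$radius_px] <- -1L
  label_raster(array(out, shape),
               as.character(seq_len(max(window_labels, 1L))),
               pixel_size_um, origin = origin)
}

#' Per-domain cell-type composition report
#'
#' @param domain_map A [label_raster()] of domains.
#' @param ctmap The `cell_type_map` the domains were derived from.
#' @return Domains x types matrix of proportions of classified pixels,
#'   rows summing to 1.
#' @export
domain_composition_report <- function(domain_map, ctmap) {
  K <- length(ctmap$labels$label_names)
  labs <- sort(unique(domain_map$labels[domain_map$labels > 0]))
  out <- t(vapply(labs, function(dl) {
    sel <- domain_map$labels == dl & ctmap$labels$labels > 0
    lab <- ctmap$labels$labels[sel]
    if (!length(lab)) return(rep(NA_real_, K))
    tabulate(lab, K) / length(lab)
  }, numeric(K)))
  dimnames(out) <- list(domain_map$label_names[labs],
                        ctmap$labels$label_names)
  out
}

#' Tissue-domain segmentation of a cell-type map
#'
#' Orchestrates [window_composition()], [cluster_compositions()],
#' [merge_domains()] and [rasterize_domains()].
#'
#' @inheritParams window_composition
#' @inheritParams merge_domains
#' @param n_initial Initial cluster count for the agglomerative step.
#' @param linkage Agglomerative linkage method.
#' @return A `domain_result` with the retained window `centers`,
#'   window `compositions` and `window_labels`, the full-resolution
#'   `domain_map`, and the per-domain `domain_compositions`.
#' @export
find_domains <- function(ctmap, radius_um = 100, step_um = 10,
                         n_initial = 15, corr_threshold = 0.8,
                         adjacency_corr_threshold = 0.6,
                         min_classified_frac = 0.01, linkage = "average") {
  wc <- window_composition(ctmap, radius_um, step_um, min_classified_frac)
  if (nrow(wc$compositions) == 0L)
    stop("no retained windows; cannot segment domains")
  init <- cluster_compositions(wc$compositions, n_initial, linkage)
  merged <- merge_domains(init, wc$compositions, corr_threshold,
                          adjacency_corr_threshold, geometry = wc)
  dmap <- rasterize_domains(merged, wc,
                            pixel_size_um = ctmap$labels$pixel_size_um,
                            origin = ctmap$labels$origin)
  structure(list(window_centers = wc$centers,
                 compositions = wc$compositions,
                 window_labels = merged, domain_map = dmap,
                 domain_compositions = domain_composition_report(dmap, ctmap),
                 params = list(radius_um = radius_um, step_um = step_um,
                               n_initial = n_initial,
                               corr_threshold = corr_threshold,
                               adjacency_corr_threshold = adjacency_corr_threshold)),
            class = "domain_result")
}

#' @export
print.domain_result <- function(x, ...) {
  cat(sprintf("domain_result: %d domains from %d windows\n",
              length(unique(x$window_labels)), length(x$window_labels)))
  invisible(x)
}
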