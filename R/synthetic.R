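# Synthetic tissue generator: layered rectangular domains, hard-core
# placed circular (spherical) cells with planted type signatures,
# negative-binomial per-cell expression and uniform intracellular spot
# placement. Provides ground truth for every pipeline stage.

#' Planted block signatures
#'
#' Each type highly expresses its own block of marker genes at
#' `mean_high` expected molecules per cell (default 25, giving
#' per-cell totals around 110 molecules, the order of magnitude
#' imaging-based protocols report) and all other genes at `mean_low`,
#' giving pairwise signature correlations near zero.
#'
#' @param n_genes Number of genes.
#' @param n_types Number of cell types.
#' @param mean_high,mean_low Expected molecules per cell for marker and
#'   non-marker genes.
#' @return A [signature_set()] (genes x types, expected counts).
#' @export
planted_signatures <- function(n_genes = 20, n_types = 5,
                               mean_high = 25, mean_low = 0.5) {
  if (n_genes < n_types) stop("need at least one marker gene per type")
  genes <- sprintf("g%02d", seq_len(n_genes))
  types <- sprintf("T%d", seq_len(n_types))
  mat <- matrix(mean_low, n_genes, n_types, dimnames = list(genes, types))
  block <- floor(n_genes / n_types)
  for (t in seq_len(n_types)) {
    rows <- ((t - 1) * block + 1):(if (t == n_types) n_genes else t * block)
    mat[rows, t] <- mean_high
  }
  signature_set(mat, types, provenance = "synthetic")
}

# Default laminar mixtures. Adjacent layers share types in graded
# proportions and one glia-like type is present everywhere (as
# astrocytes are across cortical layers), so adjacent-layer
# composition correlations are mildly positive (about +0.2) -- the
# realistic regime in which windows straddling a layer boundary still
# resemble their neighbours (r about 0.8) while the layers themselves
# stay clearly distinct.
default_layer_mixtures <- function(n_layers, n_types) {
  if (n_layers == 3L && n_types == 5L) {
    return(matrix(c(0.40, 0.20, 0.00, 0.20, 0.20,
                    0.24, 0.39, 0.16, 0.01, 0.20,
                    0.02, 0.28, 0.38, 0.12, 0.20),
                  nrow = 3, byrow = TRUE))
  }
  # general fallback: dominant type per layer, a shared ubiquitous type
  mix <- matrix(0, n_layers, n_types)
  ubiq <- if (n_types > n_layers) n_types else 0L
  main <- if (ubiq) n_types - 1L else n_types
  centers <- seq(1, main, length.out = n_layers)
  for (l in seq_len(n_layers)) {
    w <- pmax(0, 1 - abs(seq_len(main) - centers[l]) / 1.5)
    w <- w / sum(w) * if (ubiq) 0.8 else 1
    mix[l, seq_len(main)] <- w
    if (ubiq) mix[l, ubiq] <- 0.2
  }
  mix
}

# Hard-core (minimum-distance) uniform placement by dart throwing.
hardcore_points <- function(n, lower, upper, min_dist, max_tries = 200L) {
  d <- length(lower)
  pts <- matrix(NA_real_, n, d)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- stats::runif(d, lower, upper)
    ok <- placed == 0L ||
      all(rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2, cand)^2) >=
            min_dist^2)
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries * n)
        stop(sprintf("infeasible packing: placed %d of %d cells", placed, n))
    }
  }
  pts
}

#' Generate a synthetic laminar tissue
#'
#' Lays out `n_layers` rectangular layers stacked along y over a
#' `width_um` x `height_um` field (optionally extruded to `depth_um` in
#' 3D), places cells by a hard-core point process (minimum
#' centre-to-centre distance of twice the cell radius), draws each
#' cell's type from its layer's mixture, samples per-cell per-gene
#' molecule counts from a negative binomial with the planted signature
#' as mean, and scatters each molecule uniformly in the cell disc
#' (sphere in 3D). Types listed in `low_expression_types` have all
#' their expected counts scaled by `low_expression_scale`, emulating
#' cells with low total mRNA content.
#'
#' @param width_um,height_um Field extent in micrometres.
#' @param depth_um Optional extent of the third axis; `NULL` for 2D.
#' @param n_layers Number of layers (stacked along y).
#' @param signatures A [signature_set()] of expected counts per cell;
#'   default [planted_signatures()] with `n_genes` x `n_types`.
#' @param n_genes,n_types Used by the default signatures.
#' @param layer_mixtures Layers x types mixture matrix (rows sum to 1).
#' @param cells_per_100um2 Cell density per 100 square micrometres of
#'   layer area (default 0.24, about 600 cells on 500 x 500).
#' @param theta NB dispersion of per-cell counts (`Inf` for Poisson).
#' @param cell_radius_um Cell radius (default 5).
#' @param low_expression_types Type names with reduced mRNA content.
#' @param low_expression_scale Scale applied to their expected counts.
#' @param seed RNG seed; the tissue is a deterministic function of it.
#' @return A `synthetic_tissue`: `spots` ([spot_table()]),
#'   `true_signatures`, per-cell centres/radii/types/layers, the layer
#'   y-breaks, and the generating configuration.
#' @export
generate_tissue <- function(width_um = 500, height_um = 500, depth_um = NULL,
                            n_layers = 3, signatures = NULL,
                            n_genes = 20, n_types = 5,
                            layer_mixtures = NULL,
                            cells_per_100um2 = 0.24, theta = 10,
                            cell_radius_um = 5,
                            low_expression_types = NULL,
                            low_expression_scale = 0.25, seed = 1L) {
  set.seed(seed)
  signatures <- signatures %||% planted_signatures(n_genes, n_types)
  n_types <- ncol(signatures$matrix)
  n_genes <- nrow(signatures$matrix)
  layer_mixtures <- layer_mixtures %||% default_layer_mixtures(n_layers, n_types)
  if (nrow(layer_mixtures) != n_layers || ncol(layer_mixtures) != n_types)
    stop("layer_mixtures must be n_layers x n_types")
  d <- if (is.null(depth_um)) 2L else 3L
  breaks <- seq(0, height_um, length.out = n_layers + 1)
  sig <- signatures$matrix
  if (!is.null(low_expression_types)) {
    lo <- match(low_expression_types, colnames(sig))
    if (anyNA(lo)) stop("unknown low_expression_types")
    sig[, lo] <- sig[, lo] * low_expression_scale
  }
  cells <- NULL
  for (l in seq_len(n_layers)) {
    area <- width_um * (breaks[l + 1] - breaks[l])
    n_cells <- round(cells_per_100um2 * area / 100)
    if (n_cells == 0L) next
    lower <- c(cell_radius_um, breaks[l] + cell_radius_um,
               if (d == 3L) cell_radius_um)
    upper <- c(width_um - cell_radius_um, breaks[l + 1] - cell_radius_um,
               if (d == 3L) depth_um - cell_radius_um)
    if (any(upper <= lower)) stop("layer too small for the cell radius")
    pts <- hardcore_points(n_cells, lower, upper, 2 * cell_radius_um)
    types <- sample.int(n_types, n_cells, replace = TRUE,
                        prob = layer_mixtures[l, ])
    cells <- rbind(cells, cbind(pts, type = types, layer = l))
  }
  if (is.null(cells)) {
    cells <- matrix(numeric(0), 0, d + 2)
  }
  colnames(cells) <- c(c("x", "y", "z")[seq_len(d)], "type", "layer")
  spots_gene <- character(0)
  spots_xyz <- NULL
  for (ci in seq_len(nrow(cells))) {
    mu <- sig[, cells[ci, "type"]]
    counts <- if (is.infinite(theta)) stats::rpois(n_genes, mu) else
      stats::rnbinom(n_genes, mu = mu, size = theta)
    total <- sum(counts)
    if (total == 0L) next
    u <- stats::runif(total)
    r <- cell_radius_um * if (d == 2L) sqrt(u) else u^(1 / 3)
    if (d == 2L) {
      ang <- stats::runif(total, 0, 2 * pi)
      off <- cbind(r * cos(ang), r * sin(ang))
    } else {
      v <- matrix(stats::rnorm(3 * total), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      off <- v * r
    }
    pos <- sweep(off, 2, cells[ci, seq_len(d)], "+")
    spots_gene <- c(spots_gene, rep(rownames(sig), counts))
    spots_xyz <- rbind(spots_xyz, pos)
  }
  spots <- if (length(spots_gene)) spot_table(spots_gene, spots_xyz) else
    spot_table(character(0), matrix(numeric(0), 0, d))
  structure(list(spots = spots, true_signatures = signatures,
                 cells = as.data.frame(cells), layer_breaks = breaks,
                 config = list(width_um = width_um, height_um = height_um,
                               depth_um = depth_um, n_layers = n_layers,
                               layer_mixtures = layer_mixtures,
                               cells_per_100um2 = cells_per_100um2,
                               theta = theta, cell_radius_um = cell_radius_um,
                               low_expression_types = low_expression_types,
                               low_expression_scale = low_expression_scale),
                 seed = seed),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("synthetic_tissue: %d cells, %d spots, %d layers (seed %d)\n",
              nrow(x$cells), nrow(x$spots), x$config$n_layers, x$seed))
  invisible(x)
}

#' Rasterize the ground truth of a synthetic tissue
#'
#' Produces label rasters congruent with a vector field built from the
#' tissue's spots: a cell-type map (pixel centres inside a cell disc,
#' nearest cell wins on overlap) and a domain map (layer membership of
#' pixel centres inside the tissue rectangle).
#'
#' @param tissue A `synthetic_tissue`.
#' @param field The `vector_field` built from `tissue$spots`, fixing
#'   grid origin, shape and pixel size.
#' @return List with `cell_map` and `domain_map` ([label_raster()]s);
#'   `cell_map` labels index `tissue$true_signatures` types.
#' @export
rasterize_truth <- function(tissue, field) {
  shape <- field$shape
  d <- field$dim
  px <- field$pixel_size_um
  cell_lab <- rep(-1L, prod(shape))
  best_d2 <- rep(Inf, prod(shape))
  r2 <- tissue$config$cell_radius_um^2
  for (ci in seq_len(nrow(tissue$cells))) {
    ctr <- as.numeric(tissue$cells[ci, seq_len(d)])
    lo <- pmax(1L, floor((ctr - tissue$config$cell_radius_um - field$origin) / px))
    hi <- pmin(shape, ceiling((ctr + tissue$config$cell_radius_um - field$origin) / px) + 1L)
    if (any(hi < lo)) next
    ax <- lapply(seq_len(d), function(a) seq(lo[a], hi[a]))
    pix <- as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
    ctr_um <- sweep(sweep(pix - 0.5, 2, rep(px, d), "*"), 2, field$origin, "+")
    d2 <- rowSums(sweep(ctr_um, 2, ctr)^2)
    sel <- d2 <= r2
    if (!any(sel)) next
    idx <- grid_index(pix[sel, , drop = FALSE], shape)
    better <- d2[sel] < best_d2[idx]
    idx <- idx[better]
    cell_lab[idx] <- as.integer(tissue$cells[ci, "type"])
    best_d2[idx] <- d2[sel][better]
  }
  centers_y <- field$origin[2] + (seq_len(shape[2]) - 0.5) * px
  centers_x <- field$origin[1] + (seq_len(shape[1]) - 0.5) * px
  layer_of_y <- findInterval(centers_y, tissue$layer_breaks,
                             rightmost.closed = TRUE)
  layer_of_y[centers_y < 0 | centers_y > tissue$config$height_um] <- -1L
  in_x <- centers_x >= 0 & centers_x <= tissue$config$width_um
  dom2d <- outer(ifelse(in_x, 1L, -1L), layer_of_y,
                 function(a, b) ifelse(a > 0 & b > 0, b, -1L))
  dom <- array(rep(as.integer(dom2d), prod(shape) / prod(dim(dom2d))),
               shape)
  list(cell_map = label_raster(array(cell_lab, shape),
                               colnames(tissue$true_signatures$matrix),
                               px, origin = field$origin),
       domain_map = label_raster(dom,
                                 paste0("L", seq_len(tissue$config$n_layers)),
                                 px, origin = field$origin))
}
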