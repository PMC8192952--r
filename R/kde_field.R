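# Gene expression vector field: per-gene Gaussian kernel density
# estimation of mRNA spots, discretised at pixel centres and stacked
# over genes.

#' Isotropic Gaussian kernel density value
#'
#' Evaluates the variance-`h^2` Gaussian kernel
#' \deqn{\kappa_h(x) = (2\pi h^2)^{-d/2} \exp(-\|x\|^2 / (2 h^2)),}
#' which integrates to 1 over d-dimensional space.
#'
#' @param offset Length-`d` offset vector in micrometres, or a matrix of
#'   offsets (one per row).
#' @param h Kernel bandwidth in micrometres (`> 0`).
#' @param d Spatial dimension, 2 or 3.
#' @return Kernel density per micrometre^d at each offset.
#' @export
gaussian_kernel_value <- function(offset, h, d = NULL) {
  if (!is_scalar_number(h) || h <= 0) stop("bandwidth h must be > 0")
  offset <- if (is.matrix(offset)) offset else matrix(offset, nrow = 1)
  d <- d %||% ncol(offset)
  if (!d %in% c(2, 3)) stop("dimension must be 2 or 3")
  if (ncol(offset) != d) stop("offset length does not match dimension")
  r2 <- rowSums(offset^2)
  (2 * pi * h^2)^(-d / 2) * exp(-r2 / (2 * h^2))
}

#' Peak height of a single Gaussian kernel
#'
#' The density a lone mRNA molecule contributes at its own position:
#' `(2*pi*h^2)^(-d/2)`. Used as the natural unit for per-gene expression
#' thresholds and as the scale converting field values to surrogate
#' molecule counts.
#'
#' @inheritParams gaussian_kernel_value
#' @return Scalar kernel height (per micrometre^d).
#' @export
kernel_height <- function(h, d = 2) {
  if (!is_scalar_number(h) || h <= 0) stop("bandwidth h must be > 0")
  if (!d %in% c(2, 3)) stop("dimension must be 2 or 3")
  (2 * pi * h^2)^(-d / 2)
}

# Accumulate truncated Gaussian contributions of spots (micrometre
# coordinates) onto a pixel grid. Returns the raw kernel sum per pixel
# (density per um^d); callers scale by pixel area.
kde_accumulate <- function(coords, h, origin, shape, pixel_size, trunc_um) {
  d <- length(shape)
  M <- array(0, dim = shape)
  R2 <- trunc_um^2
  two_h2 <- 2 * h^2
  ax_range <- function(x, a) {
    i0 <- max(1L, ceiling((x - trunc_um - origin[a]) / pixel_size + 0.5))
    i1 <- min(shape[a], floor((x + trunc_um - origin[a]) / pixel_size + 0.5))
    c(i0, i1)
  }
  for (s in seq_len(nrow(coords))) {
    p <- coords[s, ]
    rx <- ax_range(p[1], 1); ry <- ax_range(p[2], 2)
    if (rx[1] > rx[2] || ry[1] > ry[2]) next
    dx <- origin[1] + (rx[1]:rx[2] - 0.5) * pixel_size - p[1]
    dy <- origin[2] + (ry[1]:ry[2] - 0.5) * pixel_size - p[2]
    gx <- exp(-dx^2 / two_h2); gy <- exp(-dy^2 / two_h2)
    d2xy <- outer(dx^2, dy^2, "+")
    if (d == 2L) {
      patch <- outer(gx, gy)
      patch[d2xy > R2] <- 0
      M[rx[1]:rx[2], ry[1]:ry[2]] <- M[rx[1]:rx[2], ry[1]:ry[2]] + patch
    } else {
      rz <- ax_range(p[3], 3)
      if (rz[1] > rz[2]) next
      dz <- origin[3] + (rz[1]:rz[2] - 0.5) * pixel_size - p[3]
      gz <- exp(-dz^2 / two_h2)
      base <- outer(gx, gy)
      for (ki in seq_along(gz)) {
        slab <- base * gz[ki]
        slab[d2xy + dz[ki]^2 > R2] <- 0
        k <- rz[1] + ki - 1L
        M[rx[1]:rx[2], ry[1]:ry[2], k] <- M[rx[1]:rx[2], ry[1]:ry[2], k] + slab
      }
    }
  }
  M * kernel_height(h, d)
}

# Grid covering all spots plus a margin on every side.
grid_from_spots <- function(coords, pixel_size, margin) {
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  shape <- pmax(1L, as.integer(ceiling((hi - lo) / pixel_size)))
  list(origin = lo, shape = shape)
}

#' Single-gene mRNA density raster
#'
#' Kernel density of one gene's spots, evaluated at pixel centres and
#' scaled by pixel area, so that the pixel values sum (approximately, up
#' to kernel truncation) to the gene's molecule count.
#'
#' @param spots A [spot_table()].
#' @param gene Gene name present in `spots`.
#' @param h Gaussian bandwidth in micrometres.
#' @param pixel_size Pixel edge length in micrometres.
#' @param origin,shape Grid origin (micrometres) and pixel counts per
#'   axis; derived from the spots plus a margin of `truncation_um` when
#'   omitted.
#' @param truncation_um Radial truncation of the kernel; contributions
#'   beyond this distance are zero. Must be at least `3 * h`.
#' @return Numeric array of shape `shape` (expected molecules per pixel).
#' @export
compute_density_field <- function(spots, gene, h = 2.5, pixel_size = 1,
                                  origin = NULL, shape = NULL,
                                  truncation_um = 4 * h) {
  if (truncation_um < 3 * h)
    stop("truncation radius must be at least 3 bandwidths")
  if (!gene %in% spots$gene) stop("unknown gene: ", gene)
  all_coords <- spot_coords(spots)
  if (is.null(origin) || is.null(shape)) {
    g <- grid_from_spots(all_coords, pixel_size, truncation_um)
    origin <- g$origin; shape <- g$shape
  }
  coords <- all_coords[spots$gene == gene, , drop = FALSE]
  d <- length(shape)
  kde_accumulate(coords, h, origin, shape, pixel_size, truncation_um) *
    pixel_size^d
}

#' Build the gene expression vector field
#'
#' Stacks per-gene KDE rasters over a common grid into a single array of
#' shape (X, Y\[, Z\], G): the gene expression vector field. Pixels
#' outside an optional tissue mask are zeroed.
#'
#' @param spots A [spot_table()].
#' @param h Gaussian bandwidth in micrometres (default 2.5).
#' @param pixel_size Pixel edge in micrometres (default 1).
#' @param truncation_factor Kernel truncation radius in bandwidth units
#'   (default 4).
#' @param margin_um Margin added around the spot bounding box; defaults
#'   to the truncation radius so no kernel mass falls off the grid.
#' @param mask Optional logical array over the spatial grid; pixels
#'   outside (`FALSE`) are zeroed.
#' @param genes Genes to include (default: all observed, sorted).
#' @return A `vector_field` object.
#' @export
build_vector_field <- function(spots, h = 2.5, pixel_size = 1,
                               truncation_factor = 4, margin_um = NULL,
                               mask = NULL, genes = NULL) {
  trunc_um <- truncation_factor * h
  margin_um <- margin_um %||% trunc_um
  coords <- spot_coords(spots)
  grid <- grid_from_spots(coords, pixel_size, margin_um)
  genes <- genes %||% sort(unique(spots$gene))
  d <- length(grid$shape)
  values <- array(0, dim = c(grid$shape, length(genes)))
  npix <- prod(grid$shape)
  for (gi in seq_along(genes)) {
    slice <- compute_density_field(spots, genes[gi], h = h,
                                   pixel_size = pixel_size,
                                   origin = grid$origin, shape = grid$shape,
                                   truncation_um = trunc_um)
    values[seq_len(npix) + (gi - 1) * npix] <- slice
  }
  field <- structure(
    list(values = values, genes = genes, pixel_size_um = pixel_size,
         bandwidth_um = h, dim = d, origin = grid$origin,
         shape = grid$shape, normalized = FALSE),
    class = "vector_field")
  if (!is.null(mask)) field <- apply_field_mask(field, mask)
  field
}

apply_field_mask <- function(field, mask) {
  mask <- as.array(mask)
  if (!identical(as.integer(dim(mask)), as.integer(field$shape)))
    stop("mask shape does not match the field grid")
  mat <- field_matrix(field)
  mat[!as.vector(mask), ] <- 0
  field$values <- array(mat, dim = c(field$shape, length(field$genes)))
  if (all(field$values == 0))
    warning("mask leaves no nonzero pixels in the field")
  field
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("vector_field: %s pixels x %d genes, h=%g um, pixel=%g um%s\n",
              paste(x$shape, collapse = " x "), length(x$genes),
              x$bandwidth_um, x$pixel_size_um,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

# Pixel matrix view (n_pixels x genes) of a field. Shares no state.
field_matrix <- function(field) {
  matrix(field$values, nrow = prod(field$shape),
         ncol = length(field$genes),
         dimnames = list(NULL, field$genes))
}

# Pixel vectors at integer pixel coordinates (n x d matrix), rows in order.
field_vectors_at <- function(field, coords) {
  mat <- field_matrix(field)
  mat[grid_index(coords, field$shape), , drop = FALSE]
}

#' Per-pixel L1 norm of a vector field
#'
#' Total expression per pixel: the plain sum over genes (values of an
#' unnormalized field are nonnegative, so the sum equals the L1 norm).
#'
#' @param field A raw (unnormalized) `vector_field`.
#' @return Numeric array over the spatial grid.
#' @export
field_l1_norm <- function(field) {
  if (isTRUE(field$normalized))
    stop("L1 norm is defined on the raw (unnormalized) field")
  array(rowSums(field_matrix(field)), dim = field$shape)
}

#' Write a vector field as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered gene-major (for each gene, all z-slices); values
#' are min-max scaled into the writable range with the scale recorded in
#' the sidecar (restored to 32-bit float precision on read).
#'
#' @param field A `vector_field`.
#' @param path Output TIFF path.
#' @export
write_vector_field <- function(field, path) {
  sh <- field$shape
  nz <- if (field$dim == 3L) sh[3] else 1L
  G <- length(field$genes)
  arr <- array(field$values, c(sh[1], sh[2], nz * G))
  enc <- encode_pages(arr)
  write_tiff_pages(enc$pages, path)
  write_sidecar(list(kind = "vector_field", shape = sh, genes = field$genes,
                     pixel_size_um = field$pixel_size_um,
                     bandwidth_um = field$bandwidth_um, dim = field$dim,
                     origin = field$origin, normalized = field$normalized,
                     vmin = enc$vmin, vmax = enc$vmax), path)
  invisible(path)
}

#' Read a vector field written by [write_vector_field()]
#' @param path TIFF path with its JSON sidecar alongside.
#' @return A `vector_field`.
#' @export
read_vector_field <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "vector_field"))
    stop("sidecar does not describe a vector field: ", sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- decode_pages(pages, meta$vmin, meta$vmax)
  shape <- as.integer(meta$shape)
  values <- array(unlist(pages), dim = c(shape, length(meta$genes)))
  structure(list(values = values, genes = meta$genes,
                 pixel_size_um = meta$pixel_size_um,
                 bandwidth_um = meta$bandwidth_um, dim = meta$dim,
                 origin = as.numeric(meta$origin), shape = shape,
                 normalized = isTRUE(meta$normalized)),
            class = "vector_field")
}
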