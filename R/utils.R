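# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear index into the spatial grid (column-major, 1-based), coords n x d.
grid_index <- function(coords, shape) {
  coords <- as.matrix(coords)
  d <- length(shape)
  stopifnot(ncol(coords) == d)
  idx <- coords[, 1]
  mult <- 1
  for (a in seq_len(d - 1)) {
    mult <- mult * shape[a]
    idx <- idx + (coords[, a + 1] - 1) * mult
  }
  as.integer(idx)
}

# All pixel-center coordinates (micrometres) of a grid, n_pix x d.
grid_centers_um <- function(shape, origin, pixel_size) {
  d <- length(shape)
  axes <- lapply(seq_len(d), function(a) origin[a] + (seq_len(shape[a]) - 0.5) * pixel_size)
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

# Pairwise Euclidean distances between rows of a and rows of b.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Pearson correlation between rows of x (n x g) and columns of p (g x m),
# returning an n x m matrix. Rows of x with zero variance give NA.
row_cor <- function(x, p) {
  xc <- x - rowMeans(x)
  xs <- sqrt(rowSums(xc^2))
  pc <- sweep(p, 2, colMeans(p))
  ps <- sqrt(colSums(pc^2))
  r <- (xc %*% pc) / outer(xs, ps)
  r[!is.finite(r)] <- NA_real_
  r
}

# Unit-ball volume coefficient: pi r^2 in 2D, (4/3) pi r^3 in 3D.
unit_ball_coef <- function(d) {
  switch(as.character(d), "2" = pi, "3" = 4 * pi / 3,
         stop("dimension must be 2 or 3"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
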