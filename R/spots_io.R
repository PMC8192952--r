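# Readers and writers for the external artifacts of the pipeline:
# spot tables, signature matrices, label rasters, binary masks.

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Construct a spot table
#'
#' A spot table holds one record per detected mRNA molecule: its gene
#' identity and its physical coordinates in micrometres (2D or 3D).
#'
#' @param gene Character vector of gene names, one per molecule.
#' @param coords Numeric matrix of coordinates (columns `x`, `y` and
#'   optionally `z`), in micrometres.
#' @return A `spot_table`, a `data.frame` with columns `gene`, `x`, `y`
#'   (and `z` in 3D) and attribute `ndim`.
#' @export
spot_table <- function(gene, coords) {
  coords <- as.matrix(coords)
  d <- ncol(coords)
  if (!d %in% c(2L, 3L)) stop("coordinates must have 2 or 3 columns")
  if (length(gene) != nrow(coords)) stop("gene and coords lengths differ")
  if (!all(is.finite(coords))) stop("spot coordinates must be finite")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")[seq_len(d)]
  out <- data.frame(gene = as.character(gene), coords,
                    stringsAsFactors = FALSE)
  attr(out, "ndim") <- d
  class(out) <- c("spot_table", "data.frame")
  out
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d mRNA spots, %d genes, %dD\n",
              nrow(x), length(unique(x$gene)), spot_ndim(x)))
  invisible(x)
}

#' Number of spatial dimensions of a spot table
#' @param spots A `spot_table`.
#' @return 2 or 3.
#' @export
spot_ndim <- function(spots) {
  attr(spots, "ndim") %||% (if ("z" %in% names(spots)) 3L else 2L)
}

#' Coordinate matrix of a spot table
#' @param spots A `spot_table`.
#' @return Numeric matrix, one row per spot, in micrometres.
#' @export
spot_coords <- function(spots) {
  as.matrix(spots[, c("x", "y", "z")[seq_len(spot_ndim(spots))], drop = FALSE])
}

#' Per-gene molecule counts
#' @param spots A `spot_table`.
#' @return Named integer vector of molecule counts per observed gene.
#' @export
gene_counts <- function(spots) {
  tab <- table(spots$gene)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a spot table from delimited text
#'
#' Reads a CSV/TSV with one row per detected mRNA molecule. Column names
#' are remapped through `column_map`; coordinates are multiplied by
#' `scale_um` to convert them to micrometres. Rows with non-finite
#' coordinates are dropped with a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the roles `gene`,
#'   `x`, `y` (and optionally `z`) to column names in the file.
#' @param scale_um Multiplicative factor converting file coordinates to
#'   micrometres.
#' @param sep Field separator; sniffed from the first line when `NULL`.
#' @return A [spot_table()].
#' @export
read_spots <- function(path,
                       column_map = c(gene = "gene", x = "x", y = "y", z = "z"),
                       scale_um = 1, sep = NULL) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("spot table is empty: ", path)
  cm <- as.list(column_map)
  for (role in c("gene", "x", "y")) {
    col <- cm[[role]]
    if (is.null(col) || !col %in% names(df))
      stop(sprintf("mapped column '%s' (role %s) not found in %s",
                   col %||% "<unset>", role, path))
  }
  has_z <- !is.null(cm$z) && cm$z %in% names(df)
  axes <- c(cm$x, cm$y, if (has_z) cm$z)
  coords <- sapply(df[axes], function(v) suppressWarnings(as.numeric(v)))
  coords <- matrix(coords, ncol = length(axes)) * scale_um
  ok <- rowSums(!is.finite(coords)) == 0L
  if (any(!ok))
    warning(sprintf("dropped %d spot(s) with non-finite coordinates", sum(!ok)))
  if (!any(ok)) stop("no spots with finite coordinates in ", path)
  spot_table(df[[cm$gene]][ok], coords[ok, , drop = FALSE])
}

#' Construct a set of cell-type expression signatures
#'
#' @param matrix Numeric genes x types matrix with gene row names.
#' @param type_labels Cell-type names (defaults to column names).
#' @param class_labels Optional coarse class per type (used to average
#'   signatures into prototypes).
#' @param provenance One of `"de novo"`, `"segmentation"`, `"scRNA-seq"`
#'   or a free-text origin tag.
#' @return A `signature_set` object.
#' @export
signature_set <- function(matrix, type_labels = colnames(matrix),
                          class_labels = NULL, provenance = "unknown") {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stop("signature matrix needs gene row names")
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene rows in signatures")
  if (is.null(type_labels)) type_labels <- paste0("type", seq_len(ncol(matrix)))
  if (anyDuplicated(type_labels)) stop("duplicate type labels in signatures")
  if (!is.null(class_labels) && length(class_labels) != ncol(matrix))
    stop("class_labels length must equal the number of types")
  colnames(matrix) <- type_labels
  structure(list(matrix = matrix, type_labels = as.character(type_labels),
                 class_labels = class_labels, provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d genes x %d types (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$provenance))
  invisible(x)
}

#' Read a genes x types signature matrix from delimited text
#'
#' First column holds gene names, the header row holds type labels.
#' Duplicate genes or type labels and non-numeric cells are errors.
#' Negative values are accepted (signatures may be residual-scaled).
#'
#' @inheritParams read_spots
#' @param provenance Provenance tag stored on the result.
#' @return A [signature_set()].
#' @export
read_signatures <- function(path, provenance = "unknown", sep = NULL) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("signature file needs a gene column plus >= 1 type")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene rows in ", path)
  types <- names(df)[-1]
  if (anyDuplicated(types)) stop("duplicate type labels in header of ", path)
  mat <- matrix(NA_real_, nrow(df), length(types),
                dimnames = list(genes, types))
  for (j in seq_along(types)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]) | is.na(df[[j + 1]]))
    if (length(bad))
      stop(sprintf("non-numeric signature value at row %d, column '%s'",
                   bad[1], types[j]))
    mat[, j] <- v
  }
  signature_set(mat, types, provenance = provenance)
}

#' Write a signature set as delimited text
#' @param sig A [signature_set()].
#' @param path Output CSV path.
#' @export
write_signatures <- function(sig, path) {
  df <- data.frame(gene = rownames(sig$matrix), sig$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an integer label raster
#'
#' Labels index into `label_names` (1-based); `-1` marks unclassified or
#' background pixels.
#'
#' @param labels Integer array (2D or 3D) of labels.
#' @param label_names Ordered character vector naming labels `1..K`.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param origin Physical coordinate (micrometres) of the grid corner.
#' @return A `label_raster` object.
#' @export
label_raster <- function(labels, label_names, pixel_size_um = 1,
                         origin = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  d <- length(dim(labels))
  if (!d %in% c(2L, 3L)) stop("label raster must be 2D or 3D")
  vals <- unique(as.vector(labels))
  if (!all(vals %in% c(-1L, seq_along(label_names))))
    stop("label values must be -1 or indices into label_names")
  structure(list(labels = labels, label_names = as.character(label_names),
                 pixel_size_um = pixel_size_um,
                 origin = origin %||% rep(0, d), dim = d),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("label_raster: %s pixels, %d labels, pixel %g um\n",
              paste(dim(x$labels), collapse = " x "),
              length(x$label_names), x$pixel_size_um))
  invisible(x)
}

# Min-max encode a 3D array into [0,1] pages (one per third-dim slice)
# for 32-bit float TIFF storage.
encode_pages <- function(arr) {
  rng <- range(arr)
  if (rng[2] > rng[1]) enc <- (arr - rng[1]) / (rng[2] - rng[1])
  else enc <- array(0, dim(arr))
  pages <- lapply(seq_len(dim(enc)[3]), function(k) enc[, , k])
  list(pages = pages, vmin = rng[1], vmax = rng[2])
}

decode_pages <- function(pages, vmin, vmax) {
  lapply(pages, function(p) p * (vmax - vmin) + vmin)
}

write_tiff_pages <- function(pages, path) {
  pages <- lapply(pages, function(p) {
    p <- as.matrix(p)
    p[p < 0] <- 0; p[p > 1] <- 1
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar for raster: ", sc)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write a label raster as TIFF plus JSON sidecar
#'
#' Labels are stored as one 32-bit TIFF page per z-slice, min-max scaled
#' to the writable range; the sidecar records names, pixel size, grid
#' origin and the scale so [read_label_raster()] restores the raster
#' losslessly.
#'
#' @param raster A [label_raster()].
#' @param path Output TIFF path (`<path>.json` sidecar is written too).
#' @export
write_label_raster <- function(raster, path) {
  d <- dim(raster$labels)
  nz <- if (length(d) == 3L) d[3] else 1L
  enc <- encode_pages(array(as.double(raster$labels), c(d[1], d[2], nz)))
  write_tiff_pages(enc$pages, path)
  write_sidecar(list(kind = "label_raster", shape = d,
                     label_names = raster$label_names,
                     pixel_size_um = raster$pixel_size_um,
                     origin = raster$origin, dim = raster$dim,
                     vmin = enc$vmin, vmax = enc$vmax), path)
  invisible(path)
}

#' Read a label raster written by [write_label_raster()]
#' @param path TIFF path with its JSON sidecar alongside.
#' @return A [label_raster()].
#' @export
read_label_raster <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "label_raster"))
    stop("sidecar does not describe a label raster: ", sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- decode_pages(pages, meta$vmin, meta$vmax)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  shape <- as.integer(meta$shape)
  arr <- array(as.integer(round(arr)), shape)
  label_raster(arr, meta$label_names, meta$pixel_size_um,
               origin = as.numeric(meta$origin))
}

#' Read a binary 0/1 tissue mask from TIFF
#' @param path TIFF path; multi-page files are read as 3D masks.
#' @return Logical array, `TRUE` inside the tissue.
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (dim(arr)[3] == 1L) arr <- arr[, , 1]
  arr > 0.5
}

#' Write a binary mask as 0/1 TIFF
#' @param mask Logical array (2D or 3D).
#' @param path Output TIFF path.
#' @export
write_mask <- function(mask, path) {
  d <- dim(mask)
  nz <- if (length(d) == 3L) d[3] else 1L
  arr <- array(as.double(mask), c(d[1], d[2], nz))
  pages <- lapply(seq_len(nz), function(k) arr[, , k])
  write_tiff_pages(pages, path)
  invisible(path)
}
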