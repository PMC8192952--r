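# Per-pixel cell typing: every non-background pixel of the normalized
# field is assigned the signature prototype with which its expression
# vector correlates best.

#' Average signatures into per-class prototypes
#'
#' When the signature set carries class labels, one prototype per class
#' is formed as the mean of its member signatures; otherwise the
#' signatures pass through unchanged.
#'
#' @param signatures A [signature_set()].
#' @return A [signature_set()] of prototypes.
#' @export
make_prototypes <- function(signatures) {
  cl <- signatures$class_labels
  if (is.null(cl)) return(signatures)
  classes <- unique(cl)
  proto <- vapply(classes, function(cc)
    rowMeans(signatures$matrix[, cl == cc, drop = FALSE]),
    numeric(nrow(signatures$matrix)))
  proto <- matrix(proto, nrow = nrow(signatures$matrix),
                  dimnames = list(rownames(signatures$matrix), classes))
  signature_set(proto, classes, provenance = signatures$provenance)
}

#' Classify every pixel by maximum correlation to prototypes
#'
#' For each non-background pixel, the Pearson correlation of its
#' (normalized) expression vector with every prototype is computed over
#' the genes shared by field and prototypes (aligned by name); the
#' pixel takes the label of the best-correlating prototype. Pixels that
#' are background, have zero variance, fail the optional expression
#' gate, or whose best correlation falls below `min_corr` are left
#' unclassified (`-1`). Ties are broken towards the lowest prototype
#' index.
#'
#' @param field A normalized `vector_field`.
#' @param prototypes A [signature_set()] of prototypes.
#' @param min_corr Minimum winning correlation (default 0.6).
#' @param exclude Optional logical array over the grid; `TRUE` pixels
#'   are left unclassified (used for expression gating).
#' @return A `cell_type_map`: a [label_raster()] of type labels plus
#'   the winning-correlation raster and the prototypes used.
#' @export
classify_pixels <- function(field, prototypes, min_corr = 0.6,
                            exclude = NULL) {
  if (!isTRUE(field$normalized))
    stop("classify_pixels expects a normalized field")
  shared <- intersect(field$genes, rownames(prototypes$matrix))
  if (length(shared) < 2L)
    stop("fewer than 2 genes shared between field and prototypes")
  if (length(shared) < length(field$genes) ||
      length(shared) < nrow(prototypes$matrix))
    warning(sprintf("classifying over %d shared genes", length(shared)))
  mat <- field_matrix(field)[, shared, drop = FALSE]
  P <- prototypes$matrix[shared, , drop = FALSE]
  background <- as.vector(field$background %||%
                            array(rowSums(abs(mat)) == 0, field$shape))
  valid <- !background
  if (!is.null(exclude)) {
    if (!identical(as.integer(dim(exclude)), as.integer(field$shape)))
      stop("exclude mask shape does not match the field grid")
    valid <- valid & !as.vector(exclude)
  }
  labels <- rep(-1L, nrow(mat))
  max_corr <- rep(NA_real_, nrow(mat))
  if (any(valid)) {
    R <- row_cor(mat[valid, , drop = FALSE], P)
    R[is.na(R)] <- -Inf  # zero-variance pixels stay unclassified
    win <- max.col(R, ties.method = "first")
    best <- R[cbind(seq_len(nrow(R)), win)]
    lab <- ifelse(is.finite(best) & best >= min_corr, win, -1L)
    labels[valid] <- lab
    max_corr[valid] <- ifelse(is.finite(best), best, NA_real_)
  }
  structure(list(
    labels = label_raster(array(labels, field$shape),
                          colnames(P), field$pixel_size_um,
                          origin = field$origin),
    max_corr = array(max_corr, field$shape),
    prototypes = prototypes, min_corr_threshold = min_corr),
    class = "cell_type_map")
}

#' @export
print.cell_type_map <- function(x, ...) {
  n <- sum(x$labels$labels > 0)
  cat(sprintf("cell_type_map: %s pixels, %d types, %d classified (min r %.2f)\n",
              paste(dim(x$labels$labels), collapse = " x "),
              length(x$labels$label_names), n, x$min_corr_threshold))
  invisible(x)
}

#' Guided cell-type map from prior signatures
#'
#' Averages the given signatures into per-class prototypes and
#' classifies every pixel (see [classify_pixels()]).
#'
#' @inheritParams classify_pixels
#' @param signatures A labelled [signature_set()] (e.g. from
#'   segmentation or scRNA-seq), on the same normalization scale as the
#'   field.
#' @return A `cell_type_map`.
#' @export
guided_map <- function(field, signatures, min_corr = 0.6, exclude = NULL) {
  classify_pixels(field, make_prototypes(signatures), min_corr, exclude)
}

#' De novo cell-type map from a clustering result
#'
#' Classifies pixels against the curated cluster centroids.
#'
#' @inheritParams classify_pixels
#' @param result A `cluster_result` (see [cluster_vectors()]).
#' @return A `cell_type_map`.
#' @export
de_novo_map <- function(field, result, min_corr = 0.6, exclude = NULL) {
  classify_pixels(field, result$centroids, min_corr, exclude)
}
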