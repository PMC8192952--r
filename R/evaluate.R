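# Statistics comparing a cell segmentation with a pixel cell-type map:
# the per-type matching score and the overlap / unique-region
# expression comparison.

seg_type_vector <- function(seg_types) {
  if (is.data.frame(seg_types)) {
    stats::setNames(as.character(seg_types[[2]]), seg_types[[1]])
  } else stats::setNames(as.character(seg_types), names(seg_types))
}

#' Matching score between a segmentation and a cell-type map
#'
#' For every segmented cell instance of `cell_type`, the fraction of
#' its pixels carrying the same type in the cell-type map is computed
#' (unclassified pixels count as unmatched, the denominator being the
#' full segment area). The score is the fraction of segments whose
#' matched fraction is at least `overlap_threshold` (inclusive; default
#' 10%).
#'
#' @param segmentation A [label_raster()] of cell instances (labels are
#'   instance ids).
#' @param seg_types Mapping from instance id to cell-type name: a named
#'   character vector (names = instance ids as stored in
#'   `segmentation$label_names` order index) or a two-column data frame
#'   `(instance, type)`.
#' @param ctmap A `cell_type_map` congruent with the segmentation.
#' @param cell_type Cell-type name to score.
#' @param overlap_threshold Minimum matched fraction (default 0.10).
#' @return Scalar score in `[0, 1]`.
#' @export
matching_score <- function(segmentation, seg_types, ctmap, cell_type,
                           overlap_threshold = 0.10) {
  if (!identical(dim(segmentation$labels), dim(ctmap$labels$labels)))
    stop("segmentation and cell-type map grids are not congruent")
  types <- seg_type_vector(seg_types)
  inst_ids <- which(segmentation$label_names %in%
                      names(types)[types == cell_type])
  if (!length(inst_ids))
    stop("no segment of cell type '", cell_type, "' in the segmentation")
  type_idx <- match(cell_type, ctmap$labels$label_names)
  fracs <- vapply(inst_ids, function(id) {
    pix <- segmentation$labels == id
    if (!any(pix)) return(NA_real_)
    if (is.na(type_idx)) return(0)
    mean(ctmap$labels$labels[pix] == type_idx)
  }, numeric(1))
  fracs <- fracs[!is.na(fracs)]
  if (!length(fracs))
    stop("segments of cell type '", cell_type, "' cover no pixels")
  mean(fracs >= overlap_threshold)
}

#' Partition pixels into overlap and unique regions for one cell type
#'
#' Splits the union of the segmentation footprint and the cell-type-map
#' footprint of `cell_type` into three disjoint pixel sets: the overlap
#' (ground-truth set), the segmentation-only set and the map-only set.
#'
#' @inheritParams matching_score
#' @return List of integer pixel indices: `overlap`,
#'   `segmentation_only`, `map_only`.
#' @export
overlap_partition <- function(segmentation, seg_types, ctmap, cell_type) {
  if (!identical(dim(segmentation$labels), dim(ctmap$labels$labels)))
    stop("segmentation and cell-type map grids are not congruent")
  types <- seg_type_vector(seg_types)
  inst_ids <- which(segmentation$label_names %in%
                      names(types)[types == cell_type])
  seg_fp <- which(segmentation$labels %in% inst_ids)
  type_idx <- match(cell_type, ctmap$labels$label_names)
  map_fp <- if (is.na(type_idx)) integer(0) else
    which(as.vector(ctmap$labels$labels == type_idx))
  list(overlap = intersect(seg_fp, map_fp),
       segmentation_only = setdiff(seg_fp, map_fp),
       map_only = setdiff(map_fp, seg_fp))
}

#' Correlation of unique-region vectors with the overlap mean
#'
#' Computes the mean expression vector of the overlap (ground-truth)
#' pixel set and the per-pixel Pearson correlation of every set's
#' vectors against that mean.
#'
#' @param field A normalized `vector_field`.
#' @param sets Pixel-set list from [overlap_partition()].
#' @return List of correlation vectors: `overlap`,
#'   `segmentation_only`, `map_only`.
#' @export
unique_region_correlation <- function(field, sets) {
  if (!length(sets$overlap)) stop("overlap set is empty")
  mat <- field_matrix(field)
  ref <- colMeans(mat[sets$overlap, , drop = FALSE])
  cor_set <- function(idx) {
    if (!length(idx)) return(numeric(0))
    drop(row_cor(mat[idx, , drop = FALSE], matrix(ref, ncol = 1)))
  }
  list(overlap = cor_set(sets$overlap),
       segmentation_only = cor_set(sets$segmentation_only),
       map_only = cor_set(sets$map_only))
}
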