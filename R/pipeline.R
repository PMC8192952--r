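# Parameter presets and the end-to-end pipeline orchestrator.

#' Named parameter presets
#'
#' Per-dataset parameterizations for published protocol types, plus a
#' `"synthetic"` preset scaled to the package's simulated tissues. All
#' presets share bandwidth 2.5 um, pixel 1 um, Louvain resolution 0.15
#' and SNN k = 30; they differ in the sampling thresholds, the kNN
#' density filter and the domain-merging parameters:
#'
#' * `osmfish`: gene threshold 0.027, L1 threshold 0.04, kNN filter
#'   (k = 100, density 0.002), domain window 100/10 um, 15 initial
#'   domain clusters, merges at 0.8 then 0.6 (adjacent).
#' * `merfish`: thresholds 0.0055 / 0.0035, no kNN filter, 20 initial
#'   domain clusters, merge at 0.8 (no adjacency phase), spherical
#'   window in 3D.
#' * `smfish_visp`: thresholds 0.027 / 0.2, no kNN filter, 20 initial
#'   domain clusters, merge at 0.7 (manual merging supported via
#'   [merge_clusters()]).
#' * `synthetic`: thresholds scaled to the simulated per-cell content
#'   (gene threshold of half a kernel height), domain window 50/10 um.
#'
#' @param name Preset name.
#' @return Nested parameter list with elements `kde`, `sampling`,
#'   `cluster`, `map`, `domains`.
#' @export
pipeline_preset <- function(name = c("synthetic", "osmfish", "merfish",
                                     "smfish_visp")) {
  name <- match.arg(name)
  base <- list(
    kde = list(h = 2.5, pixel_size = 1, truncation_factor = 4),
    sampling = list(window = 3L, gene_threshold = 0, l1_threshold = 0,
                    knn_k = NULL, knn_density_threshold = NULL),
    cluster = list(k = 30L, resolution = 0.15, min_corr_to_medoid = 0.6,
                   dbscan_eps = NULL),
    # classification follows the published procedure literally: pixels
    # are masked by the expression thresholds, then assigned purely by
    # maximum correlation (no correlation floor); set min_corr > 0 to
    # add a floor
    map = list(min_corr = 0, expression_gate = TRUE),
    domains = list(radius_um = 100, step_um = 10, n_initial = 15,
                   corr_threshold = 0.8, adjacency_corr_threshold = 0.6))
  over <- switch(name,
    osmfish = list(sampling = list(gene_threshold = 0.027,
                                   l1_threshold = 0.04, knn_k = 100L,
                                   knn_density_threshold = 0.002)),
    merfish = list(sampling = list(gene_threshold = 0.0055,
                                   l1_threshold = 0.0035),
                   domains = list(n_initial = 20,
                                  adjacency_corr_threshold = NULL)),
    smfish_visp = list(sampling = list(gene_threshold = 0.027,
                                       l1_threshold = 0.2),
                       domains = list(n_initial = 20, corr_threshold = 0.7,
                                      adjacency_corr_threshold = NULL)),
    synthetic = list(sampling = list(gene_threshold = kernel_height(2.5, 2) / 2,
                                     l1_threshold = 0.05),
                     domains = list(min_classified_frac = 0.2)))
  for (sec in names(over)) base[[sec]][names(over[[sec]])] <- over[[sec]]
  base$preset <- name
  base
}

#' Run the full pipeline on a spot table
#'
#' Executes all stages in order: vector-field construction (KDE),
#' local-maxima downsampling, variance-stabilizing normalization of
#' samples and field, de novo clustering (or guided classification if
#' reference signatures are supplied), pixel cell typing, and tissue
#' domain segmentation. Any stage failure aborts with the stage name;
#' artifacts computed before the failure are returned/persisted.
#'
#' @param spots A [spot_table()].
#' @param params Parameter list, see [pipeline_preset()].
#' @param seed Master seed expanded deterministically per stage.
#' @param mode `"de_novo"` (default) or `"guided"`.
#' @param reference Reference [signature_set()] (required for guided
#'   mode; used for cluster annotation in de novo mode). Guided-mode
#'   signatures must be on the Pearson-residual scale of the field, so
#'   raw references are transformed with the fitted model.
#' @param mask Optional tissue mask for the field.
#' @param out_dir Optional directory; every intermediate artifact plus
#'   a JSON provenance record is written there.
#' @return List of stage artifacts: `field` (raw), `samples` (raw),
#'   `model`, `samples_norm`, `field_norm`, `clusters`, `ctmap`,
#'   `domains`, `annotation`, `provenance`.
#' @export
run_pipeline <- function(spots, params = pipeline_preset("synthetic"),
                         seed = 0L, mode = c("de_novo", "guided"),
                         reference = NULL, mask = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "guided" && is.null(reference))
    stop("guided mode needs reference signatures")
  art <- list()
  persist <- function() {
    if (is.null(out_dir)) return(invisible())
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(art$field))
      write_vector_field(art$field, file.path(out_dir, "field.tif"))
    if (!is.null(art$samples))
      write_samples(art$samples, file.path(out_dir, "samples.csv"))
    if (!is.null(art$model))
      write_vst_model(art$model, file.path(out_dir, "model.json"))
    if (!is.null(art$field_norm))
      write_vector_field(art$field_norm, file.path(out_dir, "field_norm.tif"))
    if (!is.null(art$clusters))
      write_signatures(art$clusters$centroids,
                       file.path(out_dir, "centroids.csv"))
    if (!is.null(art$ctmap))
      write_label_raster(art$ctmap$labels, file.path(out_dir, "ctmap.tif"))
    if (!is.null(art$domains)) {
      write_label_raster(art$domains$domain_map,
                         file.path(out_dir, "domains.tif"))
      utils::write.csv(art$domains$domain_compositions,
                       file.path(out_dir, "domain_compositions.csv"))
    }
    jsonlite::write_json(art$provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible()
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  art$provenance <- list(preset = params$preset %||% "custom",
                         params = params[setdiff(names(params), "preset")],
                         seed = seed, mode = mode,
                         n_spots = nrow(spots),
                         n_genes = length(unique(spots$gene)),
                         package_version = as.character(utils::packageVersion("spotfield")),
                         timestamp = format(Sys.time(), tz = "UTC"))
  art$field <- stage("kde", do.call(build_vector_field, c(
    list(spots = spots, mask = mask),
    list(h = params$kde$h, pixel_size = params$kde$pixel_size,
         truncation_factor = params$kde$truncation_factor))))
  art$samples <- stage("sample", do.call(sample_vectors, c(
    list(field = art$field), params$sampling)))
  art$model <- stage("normalize", fit_vst_model(art$samples))
  art$samples_norm <- stage("normalize",
                            normalize_samples(art$model, art$samples))
  art$field_norm <- stage("normalize", normalize_field(art$model, art$field))
  gate <- NULL
  if (isTRUE(params$map$expression_gate)) {
    mat <- field_matrix(art$field)
    gate <- array(!(apply(mat, 1, max) >= params$sampling$gene_threshold &
                      rowSums(mat) >= params$sampling$l1_threshold),
                  art$field$shape)
  }
  if (mode == "de_novo") {
    art$clusters <- stage("cluster", cluster_vectors(
      art$samples_norm, k = params$cluster$k,
      resolution = params$cluster$resolution,
      seed = seed, dbscan_eps = params$cluster$dbscan_eps,
      min_corr_to_medoid = params$cluster$min_corr_to_medoid))
    art$ctmap <- stage("map", de_novo_map(art$field_norm, art$clusters,
                                          min_corr = params$map$min_corr,
                                          exclude = gate))
    if (!is.null(reference))
      art$annotation <- stage("map", assign_labels_to_reference(
        art$clusters$centroids, reference))
  } else {
    ref_norm <- stage("map", normalize_reference(art$model, reference))
    art$ctmap <- stage("map", guided_map(art$field_norm, ref_norm,
                                         min_corr = params$map$min_corr,
                                         exclude = gate))
  }
  art$domains <- stage("domains", do.call(find_domains, c(
    list(ctmap = art$ctmap), params$domains)))
  persist()
  art
}

# Put raw (count-scale) reference signatures on the residual scale of
# the fitted model so they are comparable with the normalized field.
normalize_reference <- function(model, reference) {
  res <- transform_vectors(model, t(reference$matrix) * model$scale)
  signature_set(t(res), reference$type_labels,
                class_labels = reference$class_labels,
                provenance = reference$provenance)
}

#' Write sampled vectors as CSV
#' @param samples A `sample_matrix`.
#' @param path Output CSV path.
#' @export
write_samples <- function(samples, path) {
  df <- data.frame(samples$pixel_coords, samples$vectors,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a fitted variance-stabilization model as JSON
#' @param model A `vst_model`.
#' @param path JSON path.
#' @export
write_vst_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_vst_model
#' @export
read_vst_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "vst_model")
}
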