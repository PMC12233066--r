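# Run configuration: YAML schema, validation, defaults, provenance hash.

schema_keys <- list(
  top = c("seed", "calibration", "conditions", "synth", "segmentation",
          "profiling", "classifier", "analyze", "output"),
  synth = c("n_cells", "length_mean", "length_sd", "width_mean", "width_sd",
            "orientation", "orientation_kappa", "curvature",
            "overlap_fraction", "min_gap_px", "frame_band_px", "background_level", "body_contrast",
            "texture_strength", "halo_strength", "halo_width_px",
            "background_gradient_amplitude", "noise_sd", "pixel_size",
            "image_shape", "seed"),
  segmentation = c("background_kernel_px", "texture_window_px",
                   "threshold_method", "threshold_value",
                   "min_object_area_px", "closing_radius_px", "connectivity"),
  # YAML 1.1 parses bare n/B-like keys as booleans, so the config file
  # uses explicit names mapped onto profiling_config(n, B)
  profiling = c("sample_size", "n_bootstrap", "min_cells_per_well",
                "max_cells_per_well", "seed", "stratify_by_well"),
  classifier = c("enabled", "categories", "n_train_bootstrap",
                 "train_sample_size", "n_trees", "mtry", "min_node",
                 "seed", "cv_grouping"),
  condition = c("name", "n_wells", "synth"),
  analyze = c("umap", "umap_n_neighbors", "umap_min_dist", "heatmap"),
  output = c("write_images", "image_format"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stopf("config: unknown key(s) in %s: %s", where, paste(bad, collapse = ", "))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file describing a full run (conditions with synthetic
#' generator overrides, segmentation, profiling, classifier, analysis and
#' output options), rejects unknown keys, applies the documented
#' defaults via the stage constructors, and computes a provenance hash.
#'
#' @param path YAML file path.
#' @return object of class \code{run_config}, with a \code{hash}
#'   attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  build_config(raw)
}

build_config <- function(raw) {
  check_keys(raw, schema_keys$top, "top level")
  for (sec in c("synth", "segmentation", "profiling", "classifier",
                "analyze", "output"))
    if (!is.null(raw[[sec]])) check_keys(raw[[sec]], schema_keys[[sec]], sec)

  seed <- as.integer(raw$seed %||% 1L)
  synth_defaults <- raw$synth %||% list()
  if (!is.null(synth_defaults$image_shape))
    synth_defaults$image_shape <- as.integer(unlist(synth_defaults$image_shape))

  conditions <- raw$conditions %||% list()
  if (!length(conditions)) stopf("config: at least one condition required")
  conditions <- lapply(conditions, function(cd) {
    check_keys(cd, schema_keys$condition, "condition")
    if (is.null(cd$name)) stopf("config: condition without a name")
    if (!is.null(cd$synth)) check_keys(cd$synth, schema_keys$synth, "condition synth")
    list(name = cd$name, n_wells = as.integer(cd$n_wells %||% 3L),
         synth = cd$synth %||% list())
  })

  prof_args <- raw$profiling %||% list()
  names(prof_args)[names(prof_args) == "sample_size"] <- "n"
  names(prof_args)[names(prof_args) == "n_bootstrap"] <- "B"
  # negative or zero sizes should fail loudly at load time
  prof <- do.call(profiling_config, modifyList(list(seed = seed), prof_args))
  seg <- do.call(segmentation_config, raw$segmentation %||% list())
  cls_raw <- raw$classifier %||% list()
  cls_enabled <- isTRUE(cls_raw$enabled)
  cls_raw$enabled <- NULL
  if (is.null(cls_raw$categories))
    cls_raw$categories <- vapply(conditions, `[[`, "", "name")
  cls <- if (cls_enabled)
    do.call(classifier_config, modifyList(list(seed = seed), cls_raw)) else NULL

  cfg <- list(seed = seed,
              calibration = raw$calibration %||% (synth_defaults$pixel_size %||% 2.0),
              conditions = conditions,
              synth_defaults = synth_defaults,
              segmentation = seg, profiling = prof,
              classifier = cls,
              analyze = list(umap = isTRUE(raw$analyze$umap),
                             umap_n_neighbors = raw$analyze$umap_n_neighbors %||% 10,
                             umap_min_dist = raw$analyze$umap_min_dist %||% 0.1,
                             heatmap = !isFALSE(raw$analyze$heatmap)),
              output = list(write_images = isTRUE(raw$output$write_images),
                            image_format = raw$output$image_format %||% "tiff"))
  attr(cfg, "hash") <- digest::digest(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Provenance hash of a configuration
#' @param cfg a \code{run_config} (or any stage config).
#' @return character digest.
#' @export
config_hash <- function(cfg) attr(cfg, "hash") %||% digest::digest(unclass(cfg))
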