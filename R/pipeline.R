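# End-to-end pipeline: simulate -> segment -> measure -> profile ->
# analyze (-> train/cv when a classifier is enabled), with a JSON
# manifest tying every output to the config hash and derived seeds.
# Rerunning with an identical config reproduces all CSV outputs
# bit-identically (figures and manifest timings excluded).

#' Run the full analysis pipeline from a configuration
#'
#' For every condition and replicate well a synthetic image is generated
#' (seeded deterministically from the global seed), segmented, and
#' measured; wells are pooled per condition, bootstrap profiles drawn,
#' and the profile matrix analyzed by PCA and correlation-distance UPGMA
#' clustering (optionally UMAP). With a classifier enabled and >= 2
#' conditions, bootstrap training sets are built from the per-condition
#' cell pools (grouped by well), a random forest is trained, and grouped
#' cross-validation is reported.
#'
#' @param config a \code{run_config} from \code{\link{load_config}}, or a
#'   path to a YAML config file.
#' @param out_dir output directory (created).
#' @param seed optional override of the config's global seed.
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$profiling$seed <- as.integer(seed)
    if (!is.null(config$classifier)) config$classifier$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list(), outputs = character(0))
  timings <- list()

  # ---- simulate + segment + measure ----
  tick <- Sys.time()
  tables <- list()   # condition -> list of cell tables
  qc <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    tables[[cond$name]] <- list()
    for (w in seq_len(cond$n_wells)) {
      sargs <- modifyList(config$synth_defaults, cond$synth)
      sargs$seed <- derive_seed(config$seed, "synth", ci, w)
      spec <- do.call(synthetic_spec, sargs)
      sim <- simulate_image(spec)
      well_id <- sprintf("%s_w%d", cond$name, w)
      if (config$output$write_images)
        write_synthetic(sim, file.path(out_dir, "images"), well_id,
                        config$output$image_format)
      lm <- segment_image(sim$image, config$segmentation, source_id = well_id)
      tb <- measure_image(lm, config$calibration, well_id, cond$name)
      tables[[cond$name]][[w]] <- tb
      qc[[well_id]] <- list(n_true_cells = nrow(sim$shapes),
                            n_regions = lm$n, config_hash = lm$config_hash)
    }
  }
  all_cells <- do.call(rbind, lapply(unlist(tables, recursive = FALSE),
                                     as.data.frame))
  rownames(all_cells) <- NULL
  cells_path <- file.path(out_dir, "cells.csv")
  write.csv(all_cells, cells_path, row.names = FALSE)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"), auto_unbox = TRUE)
  timings$segment_measure <- as.numeric(Sys.time() - tick, units = "secs")

  # ---- pool + profile ----
  tick <- Sys.time()
  pools <- list()
  pms <- list()
  for (cond in names(tables)) {
    pools[[cond]] <- pool_condition(tables[[cond]], config$profiling)
    pms[[cond]] <- bootstrap_profiles(pools[[cond]], config$profiling,
                                      condition = cond)
  }
  pm <- do.call(rbind_profiles, pms)
  profiles_path <- file.path(out_dir, "profiles.csv")
  write_profiles(pm, profiles_path)
  timings$profile <- as.numeric(Sys.time() - tick, units = "secs")

  # ---- unsupervised analysis ----
  tick <- Sys.time()
  pca <- run_pca(pm)
  write.csv(data.frame(condition = pm$meta$condition,
                       sample_id = pm$meta$sample_id,
                       pca$scores, check.names = FALSE),
            file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  write.csv(data.frame(feature = rownames(pca$loadings), pca$loadings,
                       check.names = FALSE),
            file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
  cl <- cluster_profiles(pm, k = length(config$conditions))
  write_dendrogram_newick(cl$hclust, file.path(out_dir, "dendrogram.nwk"))
  write.csv(data.frame(condition = pm$meta$condition,
                       sample_id = pm$meta$sample_id, cluster = cl$labels),
            file.path(out_dir, "clusters.csv"), row.names = FALSE)
  if (config$analyze$heatmap)
    try(plot_profile_heatmap(pm, file.path(out_dir, "heatmap.png")), silent = TRUE)
  if (config$analyze$umap && nrow(pm$features) >= 4) {
    emb <- run_umap(pm,
                    n_neighbors = min(config$analyze$umap_n_neighbors,
                                      nrow(pm$features)),
                    min_dist = config$analyze$umap_min_dist,
                    seed = derive_seed(config$seed, "umap"))
    write.csv(data.frame(condition = pm$meta$condition,
                         sample_id = pm$meta$sample_id, emb),
              file.path(out_dir, "umap.csv"), row.names = FALSE)
  }
  timings$analyze <- as.numeric(Sys.time() - tick, units = "secs")

  # ---- classifier ----
  if (!is.null(config$classifier) && length(pools) >= 2) {
    tick <- Sys.time()
    cpools <- lapply(pools, function(p) { p$group <- p$well_id; p })
    train_pm <- build_training_sets(cpools, config$classifier)
    model <- train_category_model(train_pm, config$classifier)
    write.csv(data.frame(feature = names(model$importance),
                         importance = as.numeric(model$importance)),
              file.path(out_dir, "importance.csv"), row.names = FALSE)
    cv <- tryCatch(cross_validate(train_pm, config$classifier),
                   error = function(e) { warnf("cv skipped: %s", conditionMessage(e)); NULL })
    if (!is.null(cv)) {
      write.csv(data.frame(true_category = rownames(cv$confusion),
                           cv$confusion, check.names = FALSE),
                file.path(out_dir, "confusion.csv"), row.names = FALSE)
      manifest$cv_accuracy <- cv$accuracy
    }
    manifest$oob_accuracy <- oob_accuracy(model)
    timings$classify <- as.numeric(Sys.time() - tick, units = "secs")
  }

  manifest$stages <- timings
  manifest$profiles_per_condition <-
    as.list(table(pm$meta$condition))
  manifest$cells_per_well <-
    as.list(table(all_cells$well_id))
  manifest$outputs <- list.files(out_dir, recursive = TRUE)
  manifest$elapsed_s <- as.numeric(Sys.time() - t0, units = "secs")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
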