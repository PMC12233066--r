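# Bootstrap cell-population morphological profiles.
#
# A condition's cells from triplicate wells are pooled once; B bootstrap
# samples of n cells (with replacement) are drawn; each sample is reduced
# to 12 summary statistics: the mean and the sample SD (n-1 denominator)
# of the six descriptors. Those 12-feature rows are the unit of all
# downstream comparison and classification.

#' Profiling configuration
#'
#' Defaults follow the published protocol: 10 bootstrap samples of 200
#' cells per condition; wells contribute between 200 and 5000 cells.
#'
#' @param n cells per bootstrap sample.
#' @param B bootstrap samples per condition.
#' @param min_cells_per_well wells with fewer cells are rejected.
#' @param max_cells_per_well wells with more cells are subsampled down
#'   (without replacement, seeded).
#' @param seed RNG seed for pooling and bootstrap draws.
#' @param stratify_by_well if TRUE, bootstrap draws are stratified by well
#'   of origin instead of uniform over the pool.
#' @return object of class \code{profiling_config}.
#' @export
profiling_config <- function(n = 200, B = 10, min_cells_per_well = 200,
                             max_cells_per_well = 5000, seed = 1L,
                             stratify_by_well = FALSE) {
  if (n < 2) stopf("sample size n must be >= 2")
  if (B < 1) stopf("B must be >= 1")
  if (min_cells_per_well > max_cells_per_well)
    stopf("min_cells_per_well must be <= max_cells_per_well")
  structure(list(n = as.integer(n), B = as.integer(B),
                 min_cells_per_well = as.integer(min_cells_per_well),
                 max_cells_per_well = as.integer(max_cells_per_well),
                 seed = as.integer(seed), stratify_by_well = stratify_by_well),
            class = "profiling_config")
}

#' Pool replicate wells of one condition
#'
#' Wells with fewer than \code{min_cells_per_well} cells are rejected with
#' a warning; wells above \code{max_cells_per_well} are subsampled to the
#' cap without replacement (seeded). Remaining records are concatenated
#' with their well provenance retained.
#'
#' @param tables list of \code{cell_table}s, one per replicate well.
#' @param cfg a \code{\link{profiling_config}}.
#' @return pooled \code{cell_table}.
#' @export
pool_condition <- function(tables, cfg = profiling_config()) {
  if (length(tables) < 1) stopf("pool_condition: need at least one well")
  kept <- list()
  rejected <- character(0)
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    wid <- if (nrow(tb)) tb$well_id[1] else sprintf("well%d", i)
    if (nrow(tb) < cfg$min_cells_per_well) {
      rejected <- c(rejected, sprintf("%s (%d cells)", wid, nrow(tb)))
      next
    }
    if (nrow(tb) > cfg$max_cells_per_well) {
      tb <- with_seed(derive_seed(cfg$seed, "cap", i),
                      tb[sort(sample.int(nrow(tb), cfg$max_cells_per_well)), ,
                         drop = FALSE])
      warnf("pool_condition: well %s subsampled to %d cells", wid,
            cfg$max_cells_per_well)
    }
    kept[[length(kept) + 1]] <- as.data.frame(tb)
  }
  if (length(rejected))
    warnf("pool_condition: rejected wells below %d cells: %s",
          cfg$min_cells_per_well, paste(rejected, collapse = ", "))
  if (!length(kept))
    stopf("pool_condition: all wells rejected (%s)", paste(rejected, collapse = ", "))
  pooled <- do.call(rbind, kept)
  rownames(pooled) <- NULL
  as_cell_table(pooled, attr(tables[[1]], "calibration") %||% NA_real_)
}

#' Summarize a cell sample into one 12-feature population profile
#'
#' Arithmetic mean and sample SD (n-1 denominator) of each of the six
#' descriptors, in the fixed column order of
#' \code{\link{profile_feature_names}}.
#'
#' @param sample a \code{cell_table} or data.frame with the six descriptor
#'   columns; at least 2 rows (the SD is undefined below that).
#' @return named numeric vector of length 12.
#' @export
summarize_population <- function(sample) {
  if (nrow(sample) < 2) stopf("summarize_population: need >= 2 cells")
  x <- as.matrix(sample[, DESCRIPTORS])
  setNames(c(colMeans(x), apply(x, 2, sd)), profile_feature_names())
}

#' Draw bootstrap population profiles from a pooled condition
#'
#' \code{B} samples of \code{n} cells drawn uniformly with replacement
#' (or stratified by well), each summarized via
#' \code{\link{summarize_population}}. Deterministic for a fixed
#' (pool, config): the config seed drives all draws.
#'
#' @param pool pooled \code{cell_table} (>= n cells).
#' @param cfg a \code{\link{profiling_config}}.
#' @param condition condition label for the rows (default taken from the
#'   pool).
#' @param group provenance group id stored per row (e.g. experiment).
#' @return a \code{profile_matrix}.
#' @export
bootstrap_profiles <- function(pool, cfg = profiling_config(),
                               condition = NULL, group = NA_character_) {
  np <- nrow(pool)
  if (np < cfg$n)
    stopf("bootstrap_profiles: pool has %d cells, need >= %d", np, cfg$n)
  condition <- condition %||% (if (np) pool$condition[1] else "cond")
  feats <- with_seed(derive_seed(cfg$seed, "boot", condition), {
    t(vapply(seq_len(cfg$B), function(b) {
      idx <- if (cfg$stratify_by_well) {
        unlist(lapply(split(seq_len(np), pool$well_id), function(ii)
          sample(ii, round(cfg$n * length(ii) / np), replace = TRUE)))
      } else {
        sample.int(np, cfg$n, replace = TRUE)
      }
      summarize_population(pool[idx, , drop = FALSE])
    }, numeric(12)))
  })
  meta <- data.frame(condition = condition, sample_id = seq_len(cfg$B),
                     group = group, n_cells = cfg$n,
                     wells = paste(unique(pool$well_id), collapse = ";"),
                     seed = cfg$seed, stringsAsFactors = FALSE)
  profile_matrix(feats, meta)
}

#' Construct a profile matrix
#'
#' The container for downstream analysis: a numeric matrix of profiles
#' (rows) by the 12 fixed features (columns), plus row metadata
#' (condition, bootstrap sample id, provenance group).
#'
#' @param features numeric matrix with 12 columns.
#' @param meta data.frame with one row per profile; must contain a
#'   \code{condition} column.
#' @return object of class \code{profile_matrix}.
#' @export
profile_matrix <- function(features, meta) {
  features <- as.matrix(features)
  if (ncol(features) != 12) stopf("profile matrix must have 12 columns")
  if (anyNA(features)) stopf("profile matrix must not contain missing values")
  if (nrow(meta) != nrow(features)) stopf("meta rows must match feature rows")
  if (is.null(meta$condition)) stopf("meta must contain a condition column")
  colnames(features) <- profile_feature_names()
  structure(list(features = features, meta = meta), class = "profile_matrix")
}

#' Combine profile matrices by row
#' @param ... \code{profile_matrix} objects.
#' @return a \code{profile_matrix}.
#' @export
rbind_profiles <- function(...) {
  pms <- list(...)
  feats <- do.call(rbind, lapply(pms, function(p) p$features))
  metas <- lapply(pms, function(p) p$meta)
  cols <- Reduce(intersect, lapply(metas, names))
  meta <- do.call(rbind, lapply(metas, function(m) m[, cols, drop = FALSE]))
  rownames(meta) <- NULL
  profile_matrix(feats, meta)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d profiles x %d features; conditions: %s\n",
              nrow(x$features), ncol(x$features),
              paste(unique(x$meta$condition), collapse = ", ")))
  invisible(x)
}

#' Read / write profile matrices as CSV
#'
#' The CSV carries the metadata columns first (prefixed \code{meta_}) and
#' the 12 feature columns after, so a round trip is lossless.
#'
#' @param pm a \code{profile_matrix}.
#' @param path CSV path.
#' @return \code{write_profiles}: the path, invisibly;
#'   \code{read_profiles}: a \code{profile_matrix}.
#' @export
write_profiles <- function(pm, path) {
  df <- cbind(setNames(pm$meta, paste0("meta_", names(pm$meta))),
              as.data.frame(pm$features))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  metacols <- grep("^meta_", names(df), value = TRUE)
  meta <- setNames(df[, metacols, drop = FALSE], sub("^meta_", "", metacols))
  profile_matrix(as.matrix(df[, setdiff(names(df), metacols), drop = FALSE]), meta)
}
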