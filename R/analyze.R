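# Unsupervised comparison of morphological profiles: per-feature
# z-scoring, PCA, correlation-distance average-linkage (UPGMA)
# hierarchical clustering, and UMAP embedding.

#' Standardize a profile matrix per feature
#'
#' Centers each column to mean 0 and scales to SD 1. Zero-variance
#' columns are left centered (scale 1) with a warning. The centers and
#' scales are stored as attributes so \code{\link{unstandardize}} is an
#' exact inverse.
#'
#' @param pm a \code{profile_matrix} or bare numeric matrix with >= 2 rows.
#' @return standardized numeric matrix with attributes \code{center} and
#'   \code{scale}.
#' @export
standardize <- function(pm) {
  x <- if (inherits(pm, "profile_matrix")) pm$features else as.matrix(pm)
  if (nrow(x) < 2) stopf("standardize: need >= 2 rows")
  if (anyNA(x)) stopf("standardize: missing values not allowed")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- scl == 0
  if (any(zero)) {
    warnf("standardize: zero-variance column(s) left centered: %s",
          paste(colnames(x)[zero], collapse = ", "))
    scl[zero] <- 1
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Invert \code{\link{standardize}}
#' @param z matrix returned by \code{\link{standardize}}.
#' @return the original matrix.
#' @export
unstandardize <- function(z) {
  x <- sweep(sweep(z, 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
  attr(x, "center") <- NULL; attr(x, "scale") <- NULL
  x
}

#' PCA of (standardized) profiles
#'
#' Loadings are orthonormal; explained-variance ratios are nonincreasing
#' and sum to 1 over all components. Component signs are fixed by making
#' each loading's largest-magnitude element positive, so results are
#' fully deterministic.
#'
#' @param pm a \code{profile_matrix} or numeric matrix.
#' @param standardize_input z-score features first (default TRUE).
#' @return list with \code{scores}, \code{loadings},
#'   \code{explained_variance_ratio}, and the input \code{meta} (if any).
#' @export
run_pca <- function(pm, standardize_input = TRUE) {
  meta <- if (inherits(pm, "profile_matrix")) pm$meta else NULL
  x <- if (inherits(pm, "profile_matrix")) pm$features else as.matrix(pm)
  if (nrow(x) < 2) stopf("run_pca: need >= 2 rows")
  if (standardize_input) x <- standardize(x)
  p <- prcomp(x, center = !standardize_input, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, "*")
  sco <- sweep(p$x, 2, flip, "*")
  evr <- p$sdev^2 / sum(p$sdev^2)
  list(scores = sco, loadings = rot, explained_variance_ratio = evr, meta = meta)
}

#' Pairwise correlation distance between profile rows
#'
#' \code{d(i, j) = 1 -} Pearson correlation of the two 12-feature rows;
#' range \code{[0, 2]}. Rows with zero variance across their features
#' have no defined correlation and raise an error naming the row.
#'
#' @param x numeric matrix (rows = profiles).
#' @return a \code{dist} object.
#' @export
correlation_distance <- function(x) {
  rv <- apply(x, 1, var)
  if (any(rv == 0))
    stopf("correlation distance undefined for constant row(s): %s",
          paste(which(rv == 0), collapse = ", "))
  as.dist(1 - cor(t(x)))
}

#' Hierarchical clustering of profiles (correlation distance, UPGMA)
#'
#' Average-linkage (UPGMA) clustering on \code{1 - r} correlation
#' distances between profile rows, the similarity notion used for the
#' published profile dendrograms. Deterministic: \code{\link{hclust}}
#' breaks ties by row index.
#'
#' @param pm a \code{profile_matrix} or numeric matrix.
#' @param k optional number of flat clusters to cut.
#' @param standardize_input z-score features first (default TRUE; the
#'   clustering itself is invariant to per-row affine maps, but
#'   standardization keeps features comparable, matching the heatmaps).
#' @return list with \code{hclust}, \code{dist}, and (if \code{k} given)
#'   \code{labels}.
#' @export
cluster_profiles <- function(pm, k = NULL, standardize_input = TRUE) {
  x <- if (inherits(pm, "profile_matrix")) pm$features else as.matrix(pm)
  if (nrow(x) < 2) stopf("cluster_profiles: need >= 2 rows")
  if (standardize_input) x <- standardize(x)
  d <- correlation_distance(x)
  hc <- hclust(d, method = "average")
  out <- list(hclust = hc, dist = d)
  if (!is.null(k)) out$labels <- cutree(hc, k = k)
  out
}

#' Export a profile dendrogram as Newick text
#' @param hc an \code{hclust} object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' UMAP embedding of profiles
#'
#' Thin wrapper over \code{uwot::umap} with single-threaded SGD so a
#' fixed seed gives identical coordinates on every run.
#'
#' @param pm a \code{profile_matrix} or numeric matrix with >= 4 rows.
#' @param n_neighbors UMAP neighborhood size (must be <= number of rows).
#' @param min_dist UMAP minimum embedding distance.
#' @param seed RNG seed.
#' @param standardize_input z-score features first (default TRUE).
#' @return numeric matrix (rows x 2).
#' @export
run_umap <- function(pm, n_neighbors = 15, min_dist = 0.1, seed = 42,
                     standardize_input = TRUE) {
  x <- if (inherits(pm, "profile_matrix")) pm$features else as.matrix(pm)
  if (nrow(x) < 4) stopf("run_umap: need >= 4 rows")
  if (nrow(x) < n_neighbors)
    stopf("run_umap: %d rows < n_neighbors = %d", nrow(x), n_neighbors)
  if (standardize_input) x <- standardize(x)
  emb <- with_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 0, batch = FALSE))
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' Publication-style heatmap with profile dendrogram
#'
#' Standardized profiles, rows clustered by correlation distance with
#' average linkage (columns likewise), written as a PNG.
#'
#' @param pm a \code{profile_matrix}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plot_profile_heatmap <- function(pm, path) {
  z <- standardize(pm)
  ann <- data.frame(condition = pm$meta$condition)
  rownames(z) <- rownames(ann) <-
    paste0(pm$meta$condition, "_", pm$meta$sample_id)
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(z, clustering_distance_rows = "correlation",
                     clustering_distance_cols = "correlation",
                     clustering_method = "average", annotation_row = ann,
                     silent = FALSE)
  invisible(path)
}

#' Mean silhouette width of labeled points
#'
#' Small self-contained silhouette (Euclidean) used to check that known
#' condition labels separate in an embedding.
#'
#' @param x numeric matrix of coordinates.
#' @param labels grouping vector.
#' @return mean silhouette width.
#' @export
silhouette_score <- function(x, labels) {
  labels <- as.character(labels)
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(unique(labels[!own]), function(g) mean(d[i, labels == g]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
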