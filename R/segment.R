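# Label-free segmentation of phase-contrast images.
#
# Seven-step pipeline: (1) background adjustment, (2) texture enhancement,
# (3) binarization, (4) small-object removal, (5) morphological closing,
# (6) hole filling, (7) border-object removal, followed by connected-
# component labeling. Touching cells are deliberately NOT split (no
# watershed): profiling operates on the whole population and tolerates the
# occasional merged region; the bias is documented in the vignette.

#' Segmentation pipeline configuration
#'
#' All operators the seven steps use are parameterized here; tests pin
#' explicit configs so no default is load-bearing.
#'
#' @param background_kernel_px odd mean-filter width (px) for illumination
#'   estimation; must be >= 3 and no larger than the image.
#' @param texture_window_px odd window (px) of the local-SD texture filter.
#' @param threshold_method "otsu" or "fixed".
#' @param threshold_value threshold (0..255 scale) when method is "fixed".
#' @param min_object_area_px discard components with area strictly below
#'   this (boundary inclusive: area >= min is kept). Default 100 px
#'   (~400 um^2 at 2 um/px).
#' @param closing_radius_px disk radius for morphological closing.
#' @param connectivity 4 or 8 (default) for component labeling.
#' @return object of class \code{segmentation_config}.
#' @export
segmentation_config <- function(background_kernel_px = 201,
                                texture_window_px = 9,
                                threshold_method = c("otsu", "fixed"),
                                threshold_value = NULL,
                                min_object_area_px = 100,
                                closing_radius_px = 2,
                                connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  if (background_kernel_px < 3 || background_kernel_px %% 2 == 0)
    stopf("background_kernel_px must be odd and >= 3")
  if (texture_window_px < 3 || texture_window_px %% 2 == 0)
    stopf("texture_window_px must be odd and >= 3")
  if (min_object_area_px < 1) stopf("min_object_area_px must be >= 1")
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  if (threshold_method == "fixed" && is.null(threshold_value))
    stopf("threshold_value required for fixed thresholding")
  structure(list(background_kernel_px = as.integer(background_kernel_px),
                 texture_window_px = as.integer(texture_window_px),
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_object_area_px = as.integer(min_object_area_px),
                 closing_radius_px = as.integer(closing_radius_px),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

# ---- filter primitives (integral-image box statistics) ----

pad_replicate <- function(x, p) {
  nr <- nrow(x); nc <- ncol(x)
  x[c(rep(1L, p), seq_len(nr), rep(nr, p)), c(rep(1L, p), seq_len(nc), rep(nc, p))]
}

# windowed box sum of every pixel via a summed-area table, replicate padding
box_sum <- function(x, k) {
  p <- (k - 1L) %/% 2L
  xp <- pad_replicate(x, p)
  sat <- apply(apply(xp, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- rbind(0, cbind(0, sat))                 # (nc+1) x (nr+1), transposed
  nr <- nrow(x); nc <- ncol(x)
  ri <- seq_len(nr); ci <- seq_len(nc)
  # windows in padded coords: rows ri..ri+k-1, cols ci..ci+k-1
  t(sat[ci + k, ri + k, drop = FALSE] - sat[ci, ri + k, drop = FALSE] -
      sat[ci + k, ri, drop = FALSE] + sat[ci, ri, drop = FALSE])
}

box_mean <- function(x, k) box_sum(x, k) / (k * k)

local_sd <- function(x, k) {
  m <- box_mean(x, k)
  m2 <- box_mean(x * x, k)
  sqrt(pmax(m2 - m * m, 0))
}

#' Otsu threshold of a numeric image
#'
#' Classical between-class-variance maximization over a 256-bin histogram
#' spanning the observed range. Returns \code{NA} for a constant image.
#'
#' @param x numeric matrix or vector.
#' @param n_bins histogram resolution.
#' @return threshold value, or NA if the input is constant.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps) return(NA_real_)
  h <- as.numeric(tabulate(pmin(as.integer((v - lo) / (hi - lo) * n_bins) + 1L,
                                n_bins), n_bins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  n <- w[n_bins]; mtot <- mu[n_bins]
  w1 <- w[-n_bins]; w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, n_bins - 1)
  bc[valid] <- (mtot * w1[valid] - n * mu[-n_bins][valid])^2 / (w1[valid] * w2[valid])
  kbest <- which.max(bc)  # ties -> lowest threshold
  lo + kbest / n_bins * (hi - lo)
}

disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# ---- the seven steps ----

#' Step 1: background adjustment
#'
#' Removes low-frequency illumination: output = input - smooth(input) +
#' global mean, clipped to the 0..255 gray range. The smoother is a mean
#' filter of width \code{background_kernel_px}.
#'
#' @param image numeric matrix, gray 0..255.
#' @param cfg a \code{\link{segmentation_config}}.
#' @return adjusted image.
#' @export
adjust_background <- function(image, cfg) {
  k <- cfg$background_kernel_px
  if (k > min(dim(image)))
    stopf("background kernel (%d) exceeds image size (%d x %d)",
          k, nrow(image), ncol(image))
  clamp(image - box_mean(image, k) + mean(image), 0, 255)
}

#' Step 2: texture enhancement
#'
#' Local standard deviation over \code{texture_window_px}, rescaled to the
#' full 0..255 range. Speckled cell interiors, edges, and halos score
#' high; flat background scores low. A constant image maps to all zeros.
#'
#' @inheritParams adjust_background
#' @return texture map, 0..255.
#' @export
enhance_texture <- function(image, cfg) {
  s <- local_sd(image, cfg$texture_window_px)
  hi <- max(s)
  if (hi <= 0) return(matrix(0, nrow(image), ncol(image)))
  s / hi * 255
}

#' Step 3: binarization
#'
#' Foreground = pixels strictly above the threshold (Otsu by default). A
#' constant input under Otsu falls back to an all-background mask with a
#' warning.
#'
#' @inheritParams adjust_background
#' @return logical matrix.
#' @export
binarize <- function(image, cfg) {
  thr <- if (cfg$threshold_method == "fixed") cfg$threshold_value
         else otsu_threshold(image)
  if (is.na(thr)) {
    warnf("binarize: constant image, Otsu undefined; returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  image > thr
}

#' Step 4: removal of small objects
#'
#' Deletes connected components with area strictly below
#' \code{min_object_area_px} (area >= min is kept).
#'
#' @param mask logical matrix.
#' @param cfg a \code{\link{segmentation_config}}.
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, cfg) {
  lab <- cc_label(mask, cfg$connectivity)
  n <- attr(lab, "n_labels")
  if (n == 0) return(mask)
  areas <- tabulate(lab[lab > 0L], n)
  keep <- which(areas >= cfg$min_object_area_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Steps 5-6: morphological closing, then hole filling
#'
#' Closing uses a disk of \code{closing_radius_px}; hole filling sets to
#' foreground every background component that does not touch the image
#' border (a "hole" connected to the border through a channel is kept).
#'
#' @inheritParams remove_small_objects
#' @return logical matrix.
#' @export
close_then_fill <- function(mask, cfg) {
  r <- cfg$closing_radius_px
  if (r > 0) {
    off <- disk_offsets(r)
    # dilation assumes background outside the frame; the erosion assumes
    # foreground there, so closing cannot detach frame-touching objects
    mask <- bin_morph(bin_morph(mask, off$dr, off$dc, TRUE, FALSE),
                      off$dr, off$dc, FALSE, TRUE)
  }
  bg <- cc_label(!mask, 4L)  # 4-connected background complements 8-connected fg
  nb <- attr(bg, "n_labels")
  if (nb > 0) {
    border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    hole <- bg > 0L & !(bg %in% border_labels)
    mask[hole] <- TRUE
  }
  mask
}

#' Step 7: removal of frame-touching objects
#'
#' Deletes every component with at least one pixel on the first/last row
#' or column.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
remove_border_objects <- function(mask, connectivity = 8) {
  lab <- cc_label(mask, as.integer(connectivity))
  if (attr(lab, "n_labels") == 0) return(mask)
  touching <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  touching <- touching[touching > 0L]
  if (length(touching)) mask[lab %in% touching] <- FALSE
  mask
}

#' Run the full seven-step segmentation pipeline
#'
#' Composes background adjustment, texture enhancement, binarization,
#' small-object removal, closing + hole filling, and border-object
#' removal, then labels connected components. Deterministic for a fixed
#' (image, config).
#'
#' @param image numeric matrix, gray 0..255.
#' @param cfg a \code{\link{segmentation_config}}.
#' @param source_id optional provenance string stored on the result.
#' @return object of class \code{labeled_mask}: list with \code{labels}
#'   (integer matrix, 0 background, consecutive labels from 1), \code{n}
#'   (region count), \code{config_hash}, \code{source_id}.
#' @export
segment_image <- function(image, cfg = segmentation_config(), source_id = NA_character_) {
  x <- adjust_background(image, cfg)
  x <- enhance_texture(x, cfg)
  m <- binarize(x, cfg)
  m <- remove_small_objects(m, cfg)
  m <- close_then_fill(m, cfg)
  m <- remove_small_objects(m, cfg)  # closing/filling can reshape regions
  m <- remove_border_objects(m, cfg$connectivity)
  lab <- cc_label(m, cfg$connectivity)
  structure(list(labels = lab, n = attr(lab, "n_labels"),
                 config_hash = digest::digest(unclass(cfg)),
                 source_id = source_id),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d px, %d regions (source: %s)\n",
              nrow(x$labels), ncol(x$labels), x$n, x$source_id))
  invisible(x)
}

#' Object-level segmentation scores against a ground-truth mask
#'
#' Greedy one-to-one matching of predicted to true regions at a pixel-IoU
#' threshold; reports precision, recall, and F1 (the standard instance-
#' segmentation benchmark).
#'
#' @param pred integer label matrix (prediction).
#' @param truth integer label matrix (ground truth).
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @param exclude_border drop ground-truth cells that touch the frame
#'   before scoring (default TRUE): the pipeline removes frame-touching
#'   objects by design, so they are unmatchable and not errors.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{n_matched}, \code{n_pred}, \code{n_true}.
#' @export
match_f1 <- function(pred, truth, iou_threshold = 0.5, exclude_border = TRUE) {
  if (exclude_border) {
    bt <- unique(c(truth[1, ], truth[nrow(truth), ], truth[, 1], truth[, ncol(truth)]))
    bt <- bt[bt > 0]
    if (length(bt)) {
      truth[truth %in% bt] <- 0L
      ids <- sort(unique(truth[truth > 0L]))
      remap <- integer(max(c(0L, ids))); remap[ids] <- seq_along(ids)
      truth[truth > 0L] <- remap[truth[truth > 0L]]
    }
  }
  np <- max(pred); nt <- max(truth)
  if (np == 0 || nt == 0)
    return(list(precision = 0, recall = 0, f1 = 0, n_matched = 0,
                n_pred = np, n_true = nt))
  both <- pred > 0L & truth > 0L
  inter <- table(factor(pred[both], levels = seq_len(np)),
                 factor(truth[both], levels = seq_len(nt)))
  pa <- tabulate(pred[pred > 0L], np)
  ta <- tabulate(truth[truth > 0L], nt)
  iou <- as.matrix(inter) / (outer(pa, ta, "+") - as.matrix(inter))
  matched <- 0L
  used_t <- logical(nt)
  for (i in order(-apply(iou, 1, max))) {
    j <- which.max(ifelse(used_t, -1, iou[i, ]))
    if (iou[i, j] >= iou_threshold && !used_t[j]) { used_t[j] <- TRUE; matched <- matched + 1L }
  }
  prec <- matched / np; rec <- matched / nt
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, n_matched = matched,
       n_pred = np, n_true = nt)
}
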