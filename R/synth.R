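# Synthetic phase-contrast image generator.
#
# Emulates the look of confluent myoblast/myotube cultures under 4x phase
# contrast: elongated, gently bent cells (capsules: rectangles with
# semicircular caps, optionally bowed along a circular arc), dark bodies
# with speckled interior texture, a bright 1-3 px halo rim, a low-order
# polynomial illumination gradient, and i.i.d. Gaussian sensor noise.
# Every image comes with a ground-truth instance mask, so segmentation and
# morphometry can be benchmarked without a microscope.

#' Specification of a synthetic phase-contrast image
#'
#' Defaults describe a moderately confluent field of differentiated
#' myotube-like cells at 4x magnification: a 4 mm^2 field imaged at
#' 1000 x 1000 px (2.0 um/px), cell lengths ~100 +/- 30 um and widths
#' ~16 +/- 4 um (truncated normal, length >= width enforced by swap).
#'
#' @param n_cells cells attempted per image.
#' @param length_mean,length_sd cell length distribution, um.
#' @param width_mean,width_sd cell width distribution, um.
#' @param orientation "uniform" on \code{[0, pi)} or "vonmises".
#' @param orientation_kappa von Mises concentration (ignored for uniform).
#' @param curvature maximum total bend angle (radians) of the cell
#'   centerline; each cell's bend is drawn uniformly from \code{[-c, c]}.
#' @param overlap_fraction target fraction of cells allowed to touch a
#'   neighbor, in \code{[0, 1)}; 0 guarantees disjoint instance labels.
#' @param frame_band_px if > 0, placements whose body hovers within this
#'   many pixels of the frame without clearly overhanging it are retried:
#'   windowed texture detection attaches such cells to the frame
#'   nondeterministically, which would blur the border-removal oracle.
#'   Cells that do overhang the frame remain allowed (and exercised).
#' @param min_gap_px clearance (px) kept between the bodies of
#'   non-touching cells; local-SD texture filtering and closing dilate
#'   foreground by a few pixels, so separable instances need gaps wider
#'   than roughly \code{texture_window_px / 2 + 2 * closing_radius_px}.
#' @param background_level mean background gray level.
#' @param body_contrast gray levels by which cell bodies are darker than
#'   background.
#' @param texture_strength SD (gray levels) of the speckle texture inside
#'   cell bodies; real phase-contrast cell interiors are textured, and the
#'   segmentation pipeline's texture-enhancement step relies on this.
#' @param halo_strength brightness (gray levels) of the phase halo rim.
#' @param halo_width_px halo rim thickness in pixels.
#' @param background_gradient_amplitude peak-to-peak amplitude (gray
#'   levels) of the low-order polynomial illumination gradient.
#' @param noise_sd SD of additive Gaussian sensor noise, gray levels.
#' @param pixel_size um per pixel.
#' @param image_shape integer (rows, cols).
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_cells = 300,
                           length_mean = 100, length_sd = 30,
                           width_mean = 16, width_sd = 4,
                           orientation = c("uniform", "vonmises"),
                           orientation_kappa = 2,
                           curvature = 0.8,
                           overlap_fraction = 0.05,
                           min_gap_px = 10,
                           frame_band_px = 0,
                           background_level = 150,
                           body_contrast = 60,
                           texture_strength = 12,
                           halo_strength = 30,
                           halo_width_px = 2,
                           background_gradient_amplitude = 20,
                           noise_sd = 4,
                           pixel_size = 2.0,
                           image_shape = c(1000L, 1000L),
                           seed = 1L) {
  orientation <- match.arg(orientation)
  spec <- list(n_cells = as.integer(n_cells),
               length_mean = length_mean, length_sd = length_sd,
               width_mean = width_mean, width_sd = width_sd,
               orientation = orientation, orientation_kappa = orientation_kappa,
               curvature = curvature, overlap_fraction = overlap_fraction,
               min_gap_px = min_gap_px, frame_band_px = frame_band_px,
               background_level = background_level, body_contrast = body_contrast,
               texture_strength = texture_strength,
               halo_strength = halo_strength, halo_width_px = halo_width_px,
               background_gradient_amplitude = background_gradient_amplitude,
               noise_sd = noise_sd, pixel_size = pixel_size,
               image_shape = as.integer(image_shape), seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_cells < 0) stopf("n_cells must be >= 0")
    if (length_mean <= 0 || width_mean <= 0 || pixel_size <= 0)
      stopf("all micrometer quantities must be > 0")
    if (length_sd < 0 || width_sd < 0) stopf("scale parameters must be >= 0")
    if (length_mean < width_mean) stopf("length_mean must be >= width_mean")
    if (curvature < 0) stopf("curvature must be >= 0")
    if (overlap_fraction < 0 || overlap_fraction >= 1)
      stopf("overlap_fraction must be in [0, 1)")
    if (min_gap_px < 2) stopf("min_gap_px must be >= 2 to keep labels disjoint")
    if (frame_band_px < 0) stopf("frame_band_px must be >= 0")
    if (any(image_shape <= 0) || length(image_shape) != 2)
      stopf("image_shape must be two positive integers")
    if (noise_sd < 0 || halo_strength < 0 || background_gradient_amplitude < 0 ||
        texture_strength < 0)
      stopf("gray-level amplitudes must be >= 0")
  })
  invisible(spec)
}

# truncated-at-zero normal draws (redraw; sd = 0 collapses to the mean)
rtnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

#' Sample per-cell shape parameters from a synthetic spec
#'
#' Draws \code{n_cells} (length, width, orientation, bend) tuples from the
#' distributions in the spec, using the current RNG state. Lengths and
#' widths are truncated at > 0 and length >= width is enforced by swapping.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return data.frame with columns \code{cell_id, length_um, width_um,
#'   orientation_rad, bend_rad}.
#' @export
sample_cell_shapes <- function(spec) {
  validate_synthetic_spec(spec)
  n <- spec$n_cells
  if (n == 0)
    return(data.frame(cell_id = integer(0), length_um = numeric(0),
                      width_um = numeric(0), orientation_rad = numeric(0),
                      bend_rad = numeric(0)))
  len <- rtnorm_pos(n, spec$length_mean, spec$length_sd)
  wid <- rtnorm_pos(n, spec$width_mean, spec$width_sd)
  swap <- len < wid
  tmp <- len[swap]; len[swap] <- wid[swap]; wid[swap] <- tmp
  ori <- if (spec$orientation == "uniform") runif(n, 0, pi)
         else rvonmises(n, pi / 2, spec$orientation_kappa) %% pi
  bend <- if (spec$curvature > 0) runif(n, -spec$curvature, spec$curvature)
          else rep(0, n)
  data.frame(cell_id = seq_len(n), length_um = len, width_um = wid,
             orientation_rad = ori, bend_rad = bend)
}

# centerline polyline of a (possibly bent) capsule, in pixel units,
# centered at the origin; step ~0.5 px
capsule_centerline <- function(length_px, width_px, orientation, bend) {
  h <- max((length_px - width_px) / 2, 0.5)  # half arc length of centerline
  ns <- max(2L, ceiling(2 * h / 0.5) + 1L)
  s <- seq(-h, h, length.out = ns)
  if (abs(bend) < 1e-8) {
    x <- s * cos(orientation); y <- s * sin(orientation)
  } else {
    R <- 2 * h / bend  # signed radius; total turn = bend over the centerline
    phi <- s / R
    # arc through origin, tangent at s=0 along `orientation`
    xl <- R * sin(phi)
    yl <- R * (1 - cos(phi))
    x <- xl * cos(orientation) - yl * sin(orientation)
    y <- xl * sin(orientation) + yl * cos(orientation)
  }
  cbind(x - mean(x), y - mean(y))
}

# minimum distance between two polylines (vertex-to-vertex approximation,
# adequate at 0.5 px sampling)
polyline_min_dist <- function(a, b) {
  min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
}

#' Render a synthetic phase-contrast image with ground truth
#'
#' Places the sampled cells on the canvas by rejection sampling of
#' centroids. With \code{overlap_fraction = 0} every accepted cell keeps a
#' >= 2 px clearance from all neighbors, so instance labels are disjoint;
#' larger values admit touching placements for roughly that fraction of
#' cells. Cells that cannot be placed within the retry budget are dropped
#' with a warning and are absent from the ground truth. Cells may overhang
#' the frame on purpose, to exercise border-object removal downstream.
#'
#' @param shapes data.frame from \code{\link{sample_cell_shapes}}.
#' @param spec the \code{\link{synthetic_spec}}.
#' @param max_tries placement attempts per cell.
#' @return list of class \code{synthetic_image}: \code{image} (numeric
#'   matrix, gray 0..255), \code{mask} (integer instance labels, 0 =
#'   background, consecutive from 1), \code{shapes} (ground-truth
#'   parameters of the rendered cells, in rendered order).
#' @export
render_image <- function(shapes, spec, max_tries = 150) {
  validate_synthetic_spec(spec)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  img <- matrix(spec$background_level, nr, nc)
  lab <- matrix(0L, nr, nc)

  n <- nrow(shapes)
  placed <- list()   # per placed cell: list(line = polyline, w = width_px)
  keep <- logical(n)
  centers <- matrix(NA_real_, n, 2)
  px <- spec$pixel_size

  for (i in seq_len(n)) {
    L <- shapes$length_um[i] / px
    W <- shapes$width_um[i] / px
    line0 <- capsule_centerline(L, W, shapes$orientation_rad[i], shapes$bend_rad[i])
    reach <- max(sqrt(line0[, 1]^2 + line0[, 2]^2)) + W / 2
    allow_touch <- runif(1) < spec$overlap_fraction
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cx <- runif(1, 1, nc); cy <- runif(1, 1, nr)
      line <- cbind(line0[, 1] + cx, line0[, 2] + cy)
      if (spec$frame_band_px > 0) {
        dframe <- min(line[, 1] - 1, line[, 2] - 1,
                      nc - line[, 1], nr - line[, 2]) - W / 2
        if (dframe > -0.5 && dframe < spec$frame_band_px) next
      }
      if (allow_touch) { ok <- TRUE; break }
      clear <- TRUE
      for (p in placed) {
        # cheap prune on centroid distance before the polyline check; the
        # margin must cover the clearance or near-tip pairs slip through
        if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) >
              reach + p$reach + spec$min_gap_px + 1) next
        if (polyline_min_dist(line, p$line) < (W + p$w) / 2 + spec$min_gap_px) { clear <- FALSE; break }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) next
    keep[i] <- TRUE
    centers[i, ] <- c(cx, cy)
    placed[[length(placed) + 1]] <- list(line = line, w = W, cx = cx, cy = cy,
                                         reach = reach, id = i)
  }
  if (sum(keep) < n)
    warnf("render_image: dropped %d of %d unplaceable cells", n - sum(keep), n)

  # paint in placement order; later cells overwrite earlier at overlaps
  halo_w <- spec$halo_width_px
  for (p in placed) {
    line <- p$line; W <- p$w
    pad <- W / 2 + halo_w + 1
    r0 <- max(1L, floor(min(line[, 2]) - pad)); r1 <- min(nr, ceiling(max(line[, 2]) + pad))
    c0 <- max(1L, floor(min(line[, 1]) - pad)); c1 <- min(nc, ceiling(max(line[, 1]) + pad))
    if (r0 > r1 || c0 > c1) next
    rs <- r0:r1; cs <- c0:c1
    # distance from each bbox pixel to the centerline
    dmin <- matrix(Inf, length(rs), length(cs))
    for (k in seq_len(nrow(line))) {
      d2 <- outer((rs - line[k, 2])^2, (cs - line[k, 1])^2, "+")
      dmin <- pmin(dmin, d2)
    }
    dmin <- sqrt(dmin)
    body <- dmin <= W / 2
    halo <- dmin > W / 2 & dmin <= W / 2 + halo_w
    if (!any(body)) next
    sub_lab <- lab[rs, cs, drop = FALSE]
    sub_img <- img[rs, cs, drop = FALSE]
    body_val <- spec$background_level - spec$body_contrast +
      rnorm(sum(body), 0, spec$texture_strength)
    sub_img[body] <- body_val
    sub_lab[body] <- p$id
    free_halo <- halo & sub_lab == 0L
    sub_img[free_halo] <- spec$background_level + spec$halo_strength
    lab[rs, cs] <- sub_lab
    img[rs, cs] <- sub_img
  }

  # relabel consecutively (some cells may be fully overpainted)
  ids <- sort(unique(lab[lab > 0L]))
  remap <- integer(max(c(0L, ids)))
  remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  gt <- shapes[match(ids, shapes$cell_id), , drop = FALSE]
  gt$cell_id <- seq_along(ids)
  rownames(gt) <- NULL

  # illumination gradient: low-order polynomial with seeded coefficients,
  # scaled to the requested peak-to-peak amplitude
  if (spec$background_gradient_amplitude > 0) {
    u <- matrix(rep((seq_len(nc) - 1) / max(nc - 1, 1), each = nr), nr, nc)
    v <- matrix(rep((seq_len(nr) - 1) / max(nr - 1, 1), nc), nr, nc)
    cf <- runif(5, -1, 1)
    g <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
    rg <- diff(range(g))
    if (rg > 0) img <- img + (g - min(g)) / rg * spec$background_gradient_amplitude
  }
  if (spec$noise_sd > 0) img <- img + rnorm(nr * nc, 0, spec$noise_sd)
  img <- clamp(img, 0, 255)

  structure(list(image = img, mask = lab, shapes = gt, spec = spec),
            class = "synthetic_image")
}

#' Simulate one synthetic image (sampling + rendering) under the spec seed
#'
#' @param spec a \code{\link{synthetic_spec}}; \code{spec$seed} fixes all
#'   randomness, so identical spec and seed give bit-identical output.
#' @return a \code{synthetic_image} (see \code{\link{render_image}}).
#' @export
simulate_image <- function(spec) {
  with_seed(spec$seed, {
    shapes <- sample_cell_shapes(spec)
    render_image(shapes, spec)
  })
}

#' Write a simulated image, mask, and ground-truth table to disk
#'
#' @param sim a \code{synthetic_image}.
#' @param dir output directory (created if needed).
#' @param stem file stem, e.g. \code{"well01"}.
#' @param format "tiff" (16-bit) or "png" (8-bit image; mask stays TIFF).
#' @return named character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(sim, dir, stem, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, if (format == "tiff") ".tif" else ".png"))
  if (format == "tiff") write_tiff(sim$image, img_path) else write_png(sim$image, img_path)
  mask_path <- file.path(dir, paste0(stem, "_mask.tif"))
  write_tiff(sim$mask, mask_path, bits = 16, rescale = FALSE)
  csv_path <- file.path(dir, paste0(stem, "_truth.csv"))
  write.csv(sim$shapes[, c("cell_id", "length_um", "width_um", "orientation_rad")],
            csv_path, row.names = FALSE)
  invisible(c(image = img_path, mask = mask_path, truth = csv_path))
}

#' Canonical benchmark fixture for segmentation scoring
#'
#' The pinned synthetic world used by the package's segmentation
#' benchmark: a 700 x 700 px field at 1 um/px with 60 non-touching
#' elongated cells (16 +/- 4 um wide), strong interior speckle, a 1-px
#' halo, the default illumination gradient and sensor noise. Cells never
#' touch (\code{overlap_fraction = 0}) because the pipeline deliberately
#' does not split touching instances; clearance is 14 px so texture
#' spill plus closing cannot bridge neighbors. \code{benchmark_seg_config}
#' is the matching segmentation configuration.
#'
#' @param seed RNG seed for the image.
#' @param noiseless zero out noise, gradient, halo, and (if
#'   \code{two_level}) interior texture for oracle tests.
#' @param two_level with \code{noiseless}, also remove interior texture so
#'   the render has exactly two gray levels.
#' @return a \code{\link{synthetic_spec}}.
#' @export
benchmark_spec <- function(seed = 1L, noiseless = FALSE, two_level = FALSE) {
  synthetic_spec(n_cells = 60, length_mean = 100, length_sd = 30,
                 width_mean = 16, width_sd = 4, overlap_fraction = 0,
                 min_gap_px = 14, frame_band_px = 8, texture_strength = if (noiseless && two_level) 0 else 25,
                 body_contrast = 40,
                 halo_strength = if (noiseless) 0 else 30,
                 halo_width_px = 1,
                 background_gradient_amplitude = if (noiseless) 0 else 20,
                 noise_sd = if (noiseless) 0 else 4,
                 pixel_size = 1.0, image_shape = c(700L, 700L), seed = seed)
}

#' @rdname benchmark_spec
#' @export
benchmark_seg_config <- function() {
  segmentation_config(background_kernel_px = 151, texture_window_px = 5,
                      min_object_area_px = 80, closing_radius_px = 2)
}
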