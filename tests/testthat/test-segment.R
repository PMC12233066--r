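cfg_small <- segmentation_config(background_kernel_px = 51,
                                 texture_window_px = 5,
                                 min_object_area_px = 10,
                                 closing_radius_px = 1)

test_that("config validation enforces kernel and area invariants", {
  expect_error(segmentation_config(background_kernel_px = 100), "odd")
  expect_error(segmentation_config(texture_window_px = 1), "odd")
  expect_error(segmentation_config(min_object_area_px = 0), ">= 1")
  expect_error(segmentation_config(connectivity = 6), "4 or 8")
  expect_error(segmentation_config(threshold_method = "fixed"), "threshold_value")
})

test_that("background adjustment flattens a linear gradient", {
  base <- matrix(100, 200, 200)
  grad <- outer(seq(0, 40, length.out = 200), seq(0, 20, length.out = 200), "+")
  out <- adjust_background(base + grad, cfg_small)
  expect_lt(diff(range(out)), 4)  # residual within +/- 2 gray levels
  # already-flat image passes through (up to the mean re-add)
  flat <- matrix(120, 100, 100)
  expect_equal(adjust_background(flat, cfg_small), flat)
  # kernel larger than image errors
  expect_error(adjust_background(matrix(0, 30, 30), cfg_small), "exceeds")
})

test_that("texture enhancement highlights structure, not flat field", {
  expect_true(all(enhance_texture(matrix(7, 50, 50), cfg_small) == 0))
  img <- matrix(10, 60, 60)
  img[30:32, 40:42] <- 200
  tex <- enhance_texture(img, cfg_small)
  peak <- which(tex == max(tex), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - c(31, 41))), cfg_small$texture_window_px)
  # synthetic noiseless image: response inside cells beats background
  s <- suppressWarnings(simulate_image(benchmark_spec(seed = 2, noiseless = TRUE)))
  tex2 <- enhance_texture(adjust_background(s$image, benchmark_seg_config()),
                          benchmark_seg_config())
  expect_gt(mean(tex2[s$mask > 0]), mean(tex2[s$mask == 0]))
})

test_that("binarization separates a bimodal image and falls back on constants", {
  img <- matrix(c(10, 200), 40, 40)
  m <- binarize(img, cfg_small)
  expect_identical(unname(m), unname(img > 100))
  expect_warning(m0 <- binarize(matrix(5, 20, 20), cfg_small), "constant")
  expect_false(any(m0))
})

test_that("small-object removal is boundary inclusive", {
  cfg10 <- segmentation_config(min_object_area_px = 10)
  m <- matrix(FALSE, 30, 30); m[2:6, 5] <- TRUE          # 5 px blob
  expect_false(any(remove_small_objects(m, cfg10)))
  m2 <- matrix(FALSE, 30, 30); m2[2:11, 5] <- TRUE       # exactly 10 px
  expect_identical(remove_small_objects(m2, cfg10), m2)
  # 50 blobs of sizes 1..50, min 25 -> 26 survive
  m3 <- matrix(FALSE, 60, 2 * 52)
  for (k in 1:50) m3[seq_len(k) + 2, 2 * k] <- TRUE
  cfg25 <- segmentation_config(min_object_area_px = 25)
  lab <- morphocell:::cc_label(remove_small_objects(m3, cfg25), 8L)
  expect_identical(attr(lab, "n_labels"), 26L)
})

test_that("closing merges near blobs and hole filling respects border channels", {
  cfg1 <- segmentation_config(closing_radius_px = 1, min_object_area_px = 1)
  # annulus -> solid disk
  d <- morphocell:::disk_offsets(10)
  ann <- matrix(FALSE, 41, 41)
  ann[cbind(d$dr + 21, d$dc + 21)] <- TRUE
  inner <- morphocell:::disk_offsets(5)
  ann[cbind(inner$dr + 21, inner$dc + 21)] <- FALSE
  filled <- close_then_fill(ann, cfg1)
  expect_true(all(filled[cbind(inner$dr + 21, inner$dc + 21)]))
  # two blobs 1 px apart merge under radius 1
  m <- matrix(FALSE, 20, 20)
  m[5:8, 3:6] <- TRUE; m[5:8, 8:11] <- TRUE
  lab <- morphocell:::cc_label(close_then_fill(m, cfg1), 8L)
  expect_identical(attr(lab, "n_labels"), 1L)
  # hole connected to the border through a 1-px channel stays open
  ring <- matrix(FALSE, 30, 30)
  ring[10:20, 10:20] <- TRUE
  ring[13:17, 13:17] <- FALSE            # hole
  ring[15, 1:13] <- FALSE                # channel from hole to border
  ring2 <- ring
  cfg0 <- segmentation_config(closing_radius_px = 0, min_object_area_px = 1)
  out <- close_then_fill(ring2, cfg0)
  expect_false(any(out[14:16, 14:16]))
})

test_that("border-object removal keeps interior blobs only", {
  m <- matrix(FALSE, 20, 20)
  m[8:12, 8:12] <- TRUE      # interior
  m[1, 1] <- TRUE            # corner pixel on frame
  m[2, 2] <- TRUE            # 8-connected to the corner pixel
  out <- remove_border_objects(m, 8)
  expect_true(all(out[8:12, 8:12]))
  expect_false(out[1, 1] || out[2, 2])
})

test_that("full pipeline: blank image yields no regions", {
  expect_warning(lm <- segment_image(matrix(100, 120, 120), cfg_small), "constant")
  expect_identical(lm$n, 0L)
})

test_that("full pipeline recovers interior cells exactly on noiseless input", {
  s <- suppressWarnings(simulate_image(benchmark_spec(seed = 4, noiseless = TRUE)))
  lm <- segment_image(s$image, benchmark_seg_config())
  border <- unique(c(s$mask[1, ], s$mask[nrow(s$mask), ],
                     s$mask[, 1], s$mask[, ncol(s$mask)]))
  n_interior <- max(s$mask) - sum(border > 0)
  expect_identical(lm$n, as.integer(n_interior))
})

test_that("steps 4-7 are idempotent and labels satisfy the mask contract", {
  s <- suppressWarnings(simulate_image(benchmark_spec(seed = 6)))
  cfg <- benchmark_seg_config()
  x <- enhance_texture(adjust_background(s$image, cfg), cfg)
  m <- binarize(x, cfg)
  m <- remove_small_objects(m, cfg)
  m <- close_then_fill(m, cfg)
  m <- remove_small_objects(m, cfg)
  m <- remove_border_objects(m, cfg$connectivity)
  again <- remove_border_objects(
    remove_small_objects(close_then_fill(remove_small_objects(m, cfg), cfg), cfg),
    cfg$connectivity)
  expect_identical(again, m)

  lm <- segment_image(s$image, cfg)
  expect_gt(lm$n, 0)
  areas <- tabulate(lm$labels[lm$labels > 0], lm$n)
  expect_true(all(areas >= cfg$min_object_area_px))
  expect_false(any(c(lm$labels[1, ], lm$labels[nrow(lm$labels), ],
                     lm$labels[, 1], lm$labels[, ncol(lm$labels)]) > 0))
})

test_that("pipeline is invariant to adding a constant to the image", {
  s <- suppressWarnings(simulate_image(benchmark_spec(seed = 8)))
  cfg <- benchmark_seg_config()
  a <- segment_image(s$image, cfg)
  b <- segment_image(s$image + 10, cfg)
  expect_identical(a$labels, b$labels)
})

test_that("raising the area threshold never increases the region count", {
  s <- suppressWarnings(simulate_image(benchmark_spec(seed = 10)))
  counts <- vapply(c(40, 80, 200, 500), function(a) {
    segment_image(s$image, segmentation_config(background_kernel_px = 151,
                                               texture_window_px = 5,
                                               min_object_area_px = a,
                                               closing_radius_px = 2))$n
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})
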