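test_that("profiling config enforces its invariants", {
  expect_error(profiling_config(n = 1), ">= 2")
  expect_error(profiling_config(B = 0), ">= 1")
  expect_error(profiling_config(min_cells_per_well = 300,
                                max_cells_per_well = 200), "<=")
})

test_that("pooling applies the min/max well rules", {
  set.seed(11)
  cfg <- profiling_config(min_cells_per_well = 200, max_cells_per_well = 5000)
  wells <- list(make_cells(300, well = "w1"), make_cells(300, well = "w2"),
                make_cells(300, well = "w3"))
  pool <- pool_condition(wells, cfg)
  expect_identical(nrow(pool), 900L)

  # a 150-cell well is excluded with a warning naming it
  wells2 <- list(make_cells(150, well = "tiny"), make_cells(300, well = "ok"))
  expect_warning(pool2 <- pool_condition(wells2, cfg), "tiny")
  expect_identical(nrow(pool2), 300L)

  # a 6000-cell well is capped at 5000, deterministically for the seed
  big <- list(make_cells(6000, well = "big"))
  expect_warning(pool3 <- pool_condition(big, cfg), "subsampled")
  expect_identical(nrow(pool3), 5000L)
  expect_warning(pool3b <- pool_condition(big, cfg))
  expect_identical(pool3$cell_id, pool3b$cell_id)

  # all wells rejected -> error naming them
  expect_warning(expect_error(
    pool_condition(list(make_cells(50, well = "bad1"),
                        make_cells(60, well = "bad2")), cfg),
    "bad1"))
})

test_that("summarize_population matches closed forms and a two-pass oracle", {
  two <- make_cells(2)
  two$area_um2 <- c(100, 300)
  s <- summarize_population(two)
  expect_identical(names(s), profile_feature_names())
  expect_equal(unname(s["mean_area"]), 200)
  expect_equal(unname(s["sd_area"]), sqrt(2 * 100^2), tolerance = 1e-12)

  # all-equal sample: every SD feature is zero
  same <- make_cells(5)
  same[2:5, 4:9] <- same[rep(1, 4), 4:9]
  expect_true(all(summarize_population(same)[7:12] == 0))

  expect_error(summarize_population(make_cells(1)), ">= 2")

  # independent two-pass oracle at 1e-9 relative
  set.seed(21)
  samp <- make_cells(200)
  got <- summarize_population(samp)
  cols <- c("area_um2", "perimeter_um", "length_um", "width_um",
            "lw_ratio", "compactness")
  for (j in seq_along(cols)) {
    v <- samp[[cols[j]]]
    m <- sum(v) / length(v)
    sdv <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_lt(abs(got[j] / m - 1), 1e-9)
    expect_lt(abs(got[j + 6] / sdv - 1), 1e-9)
  }
})

test_that("bootstrap profiles have the stated shape and determinism", {
  set.seed(3)
  pool <- pool_condition(list(make_cells(300, well = "w1"),
                              make_cells(300, well = "w2"),
                              make_cells(300, well = "w3")),
                         profiling_config())
  cfg <- profiling_config()   # defaults: n = 200, B = 10
  pm <- bootstrap_profiles(pool, cfg, condition = "A")
  expect_identical(dim(pm$features), c(10L, 12L))
  expect_identical(colnames(pm$features), profile_feature_names())
  expect_true(all(pm$meta$n_cells == 200L))
  expect_false(anyNA(pm$features))
  expect_true(all(pm$features[, 7:12] >= 0))

  pm2 <- bootstrap_profiles(pool, cfg, condition = "A")
  expect_identical(pm$features, pm2$features)

  expect_error(bootstrap_profiles(make_cells(100), profiling_config(n = 200)),
               "need >= 200")
})

test_that("a degenerate pool of identical cells gives zero-SD profiles", {
  one <- make_cells(200)
  one[2:200, 4:9] <- one[rep(1, 199), 4:9]
  pm <- bootstrap_profiles(one, profiling_config(n = 50, B = 5), condition = "x")
  expect_true(all(pm$features[, 7:12] == 0))
  expect_true(all(apply(pm$features[, 1:6], 2,
                        function(v) length(unique(v)) == 1)))
})

test_that("bootstrap grand means converge to pool means", {
  set.seed(17)
  pool <- make_cells(900)
  cfg <- profiling_config(n = 200, B = 500, seed = 5)
  pm <- bootstrap_profiles(pool, cfg, condition = "A")
  grand <- colMeans(pm$features)
  pool_mean <- mean(pool$length_um)
  se_boot <- sd(pm$features[, "mean_length"]) / sqrt(cfg$B)
  expect_lt(abs(grand["mean_length"] - pool_mean), 3 * se_boot)
  # variance of bootstrap means ~ pool variance / n (within 20%)
  expect_lt(abs(var(pm$features[, "mean_length"]) /
                  (var(pool$length_um) / cfg$n) - 1), 0.20)
})

test_that("profile matrices round-trip through CSV and rbind cleanly", {
  set.seed(2)
  pa <- bootstrap_profiles(make_cells(300, cond = "A"),
                           profiling_config(B = 4), condition = "A")
  pb <- bootstrap_profiles(make_cells(300, cond = "B", length_mean = 60),
                           profiling_config(B = 4), condition = "B")
  pm <- rbind_profiles(pa, pb)
  expect_identical(nrow(pm$features), 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(pm, path)
  back <- read_profiles(path)
  expect_equal(back$features, pm$features, tolerance = 1e-12)
  expect_identical(back$meta$condition, pm$meta$condition)
})

test_that("profile_matrix rejects malformed input", {
  expect_error(profile_matrix(matrix(0, 2, 11), data.frame(condition = c("a", "b"))),
               "12 columns")
  expect_error(profile_matrix(matrix(NA_real_, 2, 12),
                              data.frame(condition = c("a", "b"))), "missing")
  expect_error(profile_matrix(matrix(0, 2, 12), data.frame(x = 1:2)), "condition")
})
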