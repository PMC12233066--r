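test_that("classifier config mirrors the published design and validates", {
  cfg <- classifier_config()
  expect_length(cfg$categories, 6)
  expect_identical(cfg$n_train_bootstrap, 50L)
  expect_identical(cfg$train_sample_size, 1000L)
  expect_identical(cfg$mtry, 3L)
  expect_error(classifier_config(categories = "one"), ">= 2")
  expect_error(classifier_config(n_train_bootstrap = 1), ">= 2")
  expect_error(classifier_config(train_sample_size = 1), ">= 2")
})

test_that("training-set construction has the stated shape and determinism", {
  pools <- make_category_pools(n_per_exp = 400, seed = 2)
  cfg <- classifier_config(n_train_bootstrap = 50, train_sample_size = 1000,
                           seed = 3)
  tr <- build_training_sets(pools, cfg)
  expect_identical(dim(tr$features), c(300L, 12L))   # 6 x 50
  expect_identical(as.integer(table(tr$meta$condition)), rep(50L, 6))
  expect_identical(sort(unique(tr$meta$group)), paste0("exp", 1:5))

  tr2 <- build_training_sets(pools, cfg)
  expect_identical(tr$features, tr2$features)

  small <- classifier_config(n_train_bootstrap = 3, train_sample_size = 100,
                             seed = 1)
  tr3 <- build_training_sets(pools[1:2], small)
  expect_identical(nrow(tr3$features), 6L)

  expect_error(build_training_sets(list(a = pools[[1]][0, ], b = pools[[2]]),
                                   small), "empty")
  expect_error(build_training_sets(unname(pools), small), "named")
})

test_that("forest training: optimism, permutation null, importance contract", {
  pools <- make_category_pools(n_per_exp = 400, seed = 4)
  cfg <- classifier_config(n_train_bootstrap = 20, train_sample_size = 500,
                           n_trees = 300, seed = 7)
  tr <- build_training_sets(pools, cfg)
  model <- train_category_model(tr, cfg)

  expect_true(all(model$importance >= 0))
  expect_equal(sum(model$importance), 1, tolerance = 1e-9)
  expect_identical(names(model$importance), profile_feature_names())

  train_acc <- mean(predict_category(model, tr)$labels == tr$meta$condition)
  expect_gte(train_acc, oob_accuracy(model))

  # permuted labels: OOB accuracy within the 99% binomial interval of 1/6
  set.seed(8)
  perm <- profile_matrix(tr$features,
                         transform(tr$meta, condition = sample(condition)))
  mperm <- train_category_model(perm, cfg)
  p0 <- 1 / 6; n <- nrow(tr$features)
  half <- 2.576 * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(oob_accuracy(mperm) - p0), half + 1e-9)

  expect_error(train_category_model(
    profile_matrix(tr$features, data.frame(condition = rep("x", n))), cfg),
    ">= 2 classes")
})

test_that("duplicated feature splits importance without changing the total", {
  # independent features isolate the probe: one informative column among
  # noise, then the informative column duplicated over a noise column
  set.seed(55)
  n <- 240
  y <- rep(paste0("c", 1:4), each = n / 4)
  x <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, profile_feature_names()))
  x[, 5] <- rep(1:4 * 2, each = n / 4) + rnorm(n)
  meta <- data.frame(condition = y)
  # mtry = 12 keeps every feature in every candidate set: duplication then
  # splits impurity credit instead of inflating sampling exposure
  cfg <- classifier_config(categories = paste0("c", 1:4), n_trees = 500,
                           mtry = 12, seed = 11)
  m1 <- train_category_model(profile_matrix(x, meta), cfg)
  expect_identical(unname(which.max(m1$importance)), 5L)
  x2 <- x
  x2[, 9] <- x[, 5]
  m2 <- train_category_model(profile_matrix(x2, meta), cfg)
  expect_equal(sum(m2$importance), 1, tolerance = 1e-9)
  combined <- m2$importance[5] + m2$importance[9]
  expect_lt(abs(combined / m1$importance[5] - 1), 0.25)
})

test_that("grouped CV separates separable categories and is honest", {
  pools <- make_category_pools(n_per_exp = 500, sep = 15, seed = 6)
  cfg <- classifier_config(n_train_bootstrap = 30, train_sample_size = 800,
                           n_trees = 300, seed = 9)
  tr <- build_training_sets(pools, cfg)
  cv <- cross_validate(tr, cfg)
  expect_gte(cv$accuracy, 0.95)
  expect_equal(unname(rowSums(cv$confusion)), rep(1, 6), tolerance = 1e-9)
  expect_identical(dim(cv$confusion), c(6L, 6L))

  # labels shuffled within groups -> chance-level grouped CV
  set.seed(10)
  labs <- tr$meta$condition
  for (g in unique(tr$meta$group)) {
    ii <- tr$meta$group == g
    labs[ii] <- sample(labs[ii])
  }
  cv0 <- cross_validate(profile_matrix(tr$features,
                          data.frame(condition = labs, group = tr$meta$group)),
                        cfg)
  p0 <- 1 / 6; half <- 2.576 * sqrt(p0 * (1 - p0) / nrow(tr$features))
  expect_lt(abs(cv0$accuracy - p0), half + 1e-9)

  # a class confined to one group is refused
  meta_bad <- tr$meta
  meta_bad$group[meta_bad$condition == "cat1"] <- "exp1"
  expect_error(cross_validate(profile_matrix(tr$features, meta_bad), cfg),
               "single group")
})

test_that("prediction returns calibrated votes and checks features", {
  pools <- make_category_pools(n_per_exp = 400, seed = 12)
  cfg <- classifier_config(n_train_bootstrap = 10, train_sample_size = 300,
                           n_trees = 200, seed = 2)
  tr <- build_training_sets(pools, cfg)
  model <- train_category_model(tr, cfg)
  pr <- predict_category(model, tr)
  expect_equal(unname(rowSums(pr$probabilities)), rep(1, nrow(tr$features)),
               tolerance = 1e-12)
  # a training row is assigned its own label with above-chance probability
  i <- 25
  expect_identical(pr$labels[i], tr$meta$condition[i])
  expect_gt(pr$probabilities[i, tr$meta$condition[i]], 1 / 6)

  bad <- tr$features
  colnames(bad)[1] <- "mean_blob"
  expect_error(predict_category(model, bad), "mean_blob")
})

test_that("uniform-shift vs heterogeneity categories are both recoverable", {
  # a PG-like response: shifted means, tight spread; an NRT-like response:
  # similar means but inflated cell-to-cell heterogeneity (SD features)
  set.seed(14)
  mk <- function(cond, lmean, sdscale, e)
    as.data.frame(make_cells(500, length_mean = lmean, sd_scale = sdscale,
                             well = paste0("e", e), cond = cond,
                             group = paste0("exp", e)))
  pools <- list(
    PG  = morphocell:::as_cell_table(do.call(rbind, lapply(1:4, function(e)
      mk("PG", 110, 1, e))), 1),
    NRT = morphocell:::as_cell_table(do.call(rbind, lapply(1:4, function(e)
      mk("NRT", 95, 2.2, e))), 1))
  cfg <- classifier_config(categories = c("PG", "NRT"), n_train_bootstrap = 20,
                           train_sample_size = 500, n_trees = 300, seed = 5)
  tr <- build_training_sets(pools, cfg)
  cv <- cross_validate(tr, cfg)
  expect_gte(cv$accuracy, 0.9)
})

test_that("category recovery degrades monotonically with descriptor noise", {
  cfg <- classifier_config(n_train_bootstrap = 12, train_sample_size = 400,
                           n_trees = 200, seed = 21)
  cols <- c("area_um2", "perimeter_um", "length_um", "width_um",
            "lw_ratio", "compactness")
  acc <- vapply(c(0, 1, 10), function(noise) {
    pools <- make_category_pools(n_per_exp = 400, sep = 12, seed = 31)
    set.seed(33)
    pools <- lapply(pools, function(p) {
      for (cl in cols)
        p[[cl]] <- p[[cl]] * exp(rnorm(nrow(p), 0, noise))  # multiplicative blur
      p
    })
    cross_validate(build_training_sets(pools, cfg), cfg)$accuracy
  }, 0)
  expect_gte(acc[1], 0.95)
  expect_true(all(diff(acc) <= 0.02 + 1e-9))  # nonincreasing up to CV noise
})
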