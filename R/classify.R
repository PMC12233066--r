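# Drug-effect-category classification.
#
# For each category (cell line x drug x dose), 50 bootstrap datasets of
# 1000 cells are drawn from its single-cell pool and reduced to
# 12-feature profiles; a random forest discriminates the categories.
# Validation is grouped cross-validation: all bootstrap rows sharing a
# source-experiment group are held out together, so cells never inform
# both sides of a split.

#' Classifier configuration
#'
#' Defaults mirror the published design: six categories, 50 bootstrap
#' training datasets of 1000 cells each per category, a 500-tree forest
#' with sqrt(12) ~ 3 features per split and unlimited depth.
#'
#' @param categories ordered category labels.
#' @param n_train_bootstrap bootstrap datasets per category.
#' @param train_sample_size cells per bootstrap dataset.
#' @param n_trees trees in the forest.
#' @param mtry features tried per split (default \code{floor(sqrt(12))}).
#' @param min_node minimum node size to attempt a split.
#' @param seed RNG seed for dataset construction and forest training.
#' @param cv_grouping provenance key used to form CV groups:
#'   \code{"experiment"} (group column), \code{"well"}, or
#'   \code{"category_replicate"} (pseudo-groups over bootstrap ids, only
#'   for data without provenance; leakage-prone and warned about).
#' @return object of class \code{classifier_config}.
#' @export
classifier_config <- function(categories = c("AR-24Q+DHT", "AR-97Q+DHT",
                                             "AR-97Q+DHT+PG0.01",
                                             "AR-97Q+DHT+PG0.1",
                                             "AR-97Q+DHT+NRT1",
                                             "AR-97Q+DHT+NRT10"),
                              n_train_bootstrap = 50,
                              train_sample_size = 1000,
                              n_trees = 500, mtry = NULL, min_node = 1,
                              seed = 1L,
                              cv_grouping = c("experiment", "well",
                                              "category_replicate")) {
  cv_grouping <- match.arg(cv_grouping)
  if (length(categories) < 2) stopf("need >= 2 categories")
  if (n_train_bootstrap < 2) stopf("n_train_bootstrap must be >= 2")
  if (train_sample_size < 2) stopf("train_sample_size must be >= 2")
  structure(list(categories = categories,
                 n_train_bootstrap = as.integer(n_train_bootstrap),
                 train_sample_size = as.integer(train_sample_size),
                 n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry %||% floor(sqrt(12))),
                 min_node = as.integer(min_node), seed = as.integer(seed),
                 cv_grouping = cv_grouping),
            class = "classifier_config")
}

#' Build bootstrap training profiles from per-category cell pools
#'
#' For each category, draws \code{n_train_bootstrap} samples of
#' \code{train_sample_size} cells with replacement from the category's
#' pool and reduces each to a 12-feature profile. When the pool has a
#' \code{group} column (source experiment), each bootstrap dataset is
#' drawn from a single group and tagged with it, cycling over groups;
#' otherwise all rows share one group per category. Sampling with
#' replacement is valid for pools smaller than the sample size, but a
#' pool below half of \code{train_sample_size} triggers a warning.
#'
#' @param pools named list: category label -> \code{cell_table} (rows may
#'   carry a \code{group} column).
#' @param cfg a \code{\link{classifier_config}}.
#' @return a \code{profile_matrix} whose meta has columns
#'   \code{condition}, \code{sample_id}, \code{group}.
#' @export
build_training_sets <- function(pools, cfg = classifier_config()) {
  if (is.null(names(pools)) || any(names(pools) == ""))
    stopf("pools must be a named list (category -> cell table)")
  out <- list()
  for (cat in names(pools)) {
    pool <- pools[[cat]]
    if (is.null(pool) || nrow(pool) == 0) stopf("empty cell pool for category '%s'", cat)
    groups <- if (!is.null(pool$group)) sort(unique(pool$group)) else cat
    by_group <- if (!is.null(pool$group)) split(seq_len(nrow(pool)), pool$group)
                else list(seq_len(nrow(pool)))
    names(by_group) <- groups
    small <- vapply(by_group, length, 0L) < cfg$train_sample_size / 2
    if (any(small))
      warnf("category '%s': pool group(s) below %d cells: %s", cat,
            as.integer(cfg$train_sample_size / 2),
            paste(groups[small], collapse = ", "))
    feats <- matrix(NA_real_, cfg$n_train_bootstrap, 12)
    grp <- character(cfg$n_train_bootstrap)
    with_seed(derive_seed(cfg$seed, "train", cat), {
      for (b in seq_len(cfg$n_train_bootstrap)) {
        g <- groups[((b - 1) %% length(groups)) + 1]
        rows <- by_group[[as.character(g)]]
        idx <- rows[sample.int(length(rows), cfg$train_sample_size, replace = TRUE)]
        feats[b, ] <- summarize_population(pool[idx, , drop = FALSE])
        grp[b] <- as.character(g)
      }
    })
    out[[cat]] <- profile_matrix(feats,
      data.frame(condition = cat, sample_id = seq_len(cfg$n_train_bootstrap),
                 group = grp, stringsAsFactors = FALSE))
  }
  do.call(rbind_profiles, out)
}

#' Train the drug-effect-category random forest
#'
#' Fits the in-package CART/Gini random forest (bootstrap bagging, mtry
#' feature subsampling) on 12-feature profiles. Stores normalized
#' impurity-based feature importances (nonnegative, summing to 1) and
#' out-of-bag votes.
#'
#' @param pm a \code{profile_matrix} with >= 2 distinct conditions, or a
#'   bare feature matrix (then \code{labels} is required).
#' @param cfg a \code{\link{classifier_config}}.
#' @param labels class labels (defaults to \code{pm$meta$condition}).
#' @return object of class \code{category_model}.
#' @export
train_category_model <- function(pm, cfg = classifier_config(), labels = NULL) {
  x <- if (inherits(pm, "profile_matrix")) pm$features else as.matrix(pm)
  labels <- labels %||% pm$meta$condition
  if (ncol(x) != 12) stopf("expected 12 features, got %d", ncol(x))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stopf("training requires >= 2 classes")
  y <- match(as.character(labels), classes) - 1L
  fit <- rf_train_cpp(x, y, length(classes), cfg$n_trees, cfg$mtry,
                      cfg$min_node, derive_seed(cfg$seed, "forest"))
  importance <- setNames(as.numeric(fit$importance), colnames(x))
  oob <- fit$oob_votes
  colnames(oob) <- classes
  structure(list(trees = fit$trees, classes = classes,
                 feature_names = colnames(x), importance = importance,
                 oob_votes = oob, labels = as.character(labels),
                 n_trees = cfg$n_trees,
                 config_hash = digest::digest(unclass(cfg))),
            class = "category_model")
}

#' @export
print.category_model <- function(x, ...) {
  cat(sprintf("<category_model> %d-tree random forest, %d classes\n",
              x$n_trees, length(x$classes)))
  acc <- oob_accuracy(x)
  if (!is.na(acc)) cat(sprintf("  OOB accuracy: %.3f\n", acc))
  invisible(x)
}

#' Out-of-bag accuracy of a trained category model
#' @param model a \code{category_model}.
#' @return OOB accuracy (NA if some rows were never out of bag).
#' @export
oob_accuracy <- function(model) {
  v <- model$oob_votes
  if (any(rowSums(v) == 0)) return(NA_real_)
  pred <- model$classes[max.col(v, ties.method = "first")]
  mean(pred == model$labels)
}

#' Predict drug-effect categories for new profiles
#'
#' @param model a \code{category_model}.
#' @param pm a \code{profile_matrix} or feature matrix whose columns match
#'   the model's features (mismatches raise an error listing differences).
#' @return list with \code{labels} (argmax of forest votes, ties to the
#'   first class) and \code{probabilities} (vote fractions; rows sum to 1).
#' @export
predict_category <- function(model, pm) {
  x <- if (inherits(pm, "profile_matrix")) pm$features else as.matrix(pm)
  if (!identical(colnames(x), model$feature_names)) {
    miss <- setdiff(model$feature_names, colnames(x))
    extra <- setdiff(colnames(x), model$feature_names)
    stopf("feature mismatch; missing: [%s], unexpected: [%s]",
          paste(miss, collapse = ", "), paste(extra, collapse = ", "))
  }
  votes <- rf_votes_cpp(model$trees, x, length(model$classes))
  probs <- votes / rowSums(votes)
  colnames(probs) <- model$classes
  list(labels = model$classes[max.col(probs, ties.method = "first")],
       probabilities = probs)
}

#' Grouped cross-validation of the category classifier
#'
#' Folds are the unique provenance groups: every row sharing a group id
#' (bootstrap datasets built from the same source experiment) is held out
#' together, preventing leakage of cells across the split. Returns the
#' row-normalized confusion matrix (true categories x predicted) and
#' overall accuracy.
#'
#' @param pm a \code{profile_matrix} whose meta carries \code{condition}
#'   and \code{group}.
#' @param cfg a \code{\link{classifier_config}}.
#' @param groups optional explicit group vector overriding the meta.
#' @return list with \code{confusion} (rows sum to 1), \code{accuracy},
#'   \code{fold_accuracy}, \code{predictions}.
#' @export
cross_validate <- function(pm, cfg = classifier_config(), groups = NULL) {
  x <- pm$features
  labels <- as.character(pm$meta$condition)
  groups <- as.character(groups %||% pm$meta$group)
  if (anyNA(groups)) stopf("cross_validate: missing group ids")
  tab <- table(labels, groups)
  confined <- rownames(tab)[rowSums(tab > 0) < 2]
  if (length(confined))
    stopf(paste("class(es) confined to a single group: %s;",
                "grouped CV would leak the group into every training fold"),
          paste(confined, collapse = ", "))
  classes <- sort(unique(labels))
  pred <- character(length(labels))
  fold_acc <- setNames(numeric(0), character(0))
  for (g in sort(unique(groups))) {
    hold <- groups == g
    model <- train_category_model(
      profile_matrix(x[!hold, , drop = FALSE],
                     data.frame(condition = labels[!hold])), cfg)
    p <- predict_category(model, x[hold, , drop = FALSE])
    pred[hold] <- p$labels
    fold_acc[g] <- mean(p$labels == labels[hold])
  }
  cm <- table(factor(labels, classes), factor(pred, classes))
  cm <- sweep(as.matrix(cm), 1, pmax(rowSums(cm), 1), "/")
  list(confusion = cm, accuracy = mean(pred == labels),
       fold_accuracy = fold_acc, predictions = pred)
}
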