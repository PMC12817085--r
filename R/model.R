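#' Random-forest configuration
#'
#' Hyperparameter grids and defaults for the pathogenicity classifier:
#' `mtry` (features tried per split) in \{2, 5, 10, 15, 20\}, `ntree` in
#' \{20, 50, 100, 200, 300, 400\}, `max_node` (terminal-node cap per tree)
#' in \{5, 10, 20, 30\}, five cross-validation folds. The shipped defaults
#' (`mtry = 20`, `ntree = 200`, `max_node = 30`) are the grid optimum for
#' the published training cohort.
#'
#' @param mtry_grid,ntree_grid,max_node_grid Non-empty integer grids.
#' @param folds Number of CV folds (>= 2).
#' @param mtry,ntree,max_node Default hyperparameters.
#' @return A list of class `"forest_config"`.
#' @export
forest_config <- function(mtry_grid = c(2, 5, 10, 15, 20),
                          ntree_grid = c(20, 50, 100, 200, 300, 400),
                          max_node_grid = c(5, 10, 20, 30),
                          folds = 5L,
                          mtry = 20L, ntree = 200L, max_node = 30L) {
  stopifnot(length(mtry_grid) > 0, length(ntree_grid) > 0,
            length(max_node_grid) > 0, folds >= 2)
  structure(list(mtry_grid = as.integer(mtry_grid),
                 ntree_grid = as.integer(ntree_grid),
                 max_node_grid = as.integer(max_node_grid),
                 folds = as.integer(folds),
                 mtry = as.integer(mtry), ntree = as.integer(ntree),
                 max_node = as.integer(max_node)),
            class = "forest_config")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "P", "B")
  labels <- as.character(labels)
  if (!all(labels %in% c("B", "P")))
    stop('labels must be "B"/"P" (or logical pathogenic flags)', call. = FALSE)
  factor(labels, levels = c("B", "P"))
}

# Stratified k-fold partition: class ratios preserved per fold; every row in
# exactly one validation fold.
cv_folds <- function(labels, k, seed) {
  y <- as_binary_labels(labels)
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the random-forest pathogenicity classifier
#'
#' Fits imputation medians on the training rows, then grows a
#' probability-voting forest: the score of a variant is the fraction of
#' trees voting pathogenic, i.e. the mean of per-tree outputs, in `[0, 1]`.
#' `max_node` caps the number of terminal nodes of each tree.
#'
#' @param x Feature data frame (columns in [feature_registry()] order for
#'   pipeline use; any fixed numeric registry is accepted).
#' @param labels `"B"`/`"P"` vector (or logical pathogenic flags).
#' @param mtry,ntree,max_node Hyperparameters (default: shipped optimum).
#' @param seed Integer seed governing all forest randomness.
#' @return An object of class `"trained_forest"`.
#' @export
train_forest <- function(x, labels, mtry = 20L, ntree = 200L,
                         max_node = 30L, seed = 1L) {
  x <- as.data.frame(x)
  y <- as_binary_labels(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present in the training labels", call. = FALSE)
  imp <- impute_median(x)
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = imp$imputed, y = y,
    mtry = min(mtry, ncol(x)), ntree = ntree,
    maxnodes = min(max_node, nrow(x)))  # a tree cannot have more leaves than rows
  structure(list(forest = rf, medians = imp$medians,
                 registry = colnames(x),
                 config = list(mtry = mtry, ntree = ntree,
                               max_node = max_node),
                 seed = seed, n_train = nrow(x)),
            class = "trained_forest")
}

#' @export
print.trained_forest <- function(x, ...) {
  cat(sprintf(
    "<trained_forest: %d trees, mtry %d, max %d terminal nodes, %d features, n = %d>\n",
    x$config$ntree, x$config$mtry, x$config$max_node,
    length(x$registry), x$n_train))
  invisible(x)
}

#' Score variants with a trained forest
#'
#' Missing feature values are filled with the medians stored at training
#' time; the feature registry must match the model's exactly.
#'
#' @param object A `trained_forest`.
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]` (fraction of trees voting pathogenic).
#' @export
predict.trained_forest <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!identical(colnames(newdata), object$registry))
    stop("feature registry mismatch between model and input", call. = FALSE)
  filled <- apply_medians(newdata, object$medians)
  unname(predict(object$forest, filled, type = "prob")[, "P"])
}

#' Grid-searched cross-validated hyperparameter selection
#'
#' Evaluates every point of the `mtry` x `ntree` x `max_node` grid by mean
#' out-of-fold AUROC under stratified k-fold cross-validation (imputation
#' medians refitted inside each training fold), and returns the maximizer.
#' Ties are broken toward smaller `ntree`, then smaller `max_node`, then
#' smaller `mtry`. Deterministic given `seed`.
#'
#' @param x Feature data frame.
#' @param labels `"B"`/`"P"` vector.
#' @param config A [forest_config()].
#' @param seed Integer seed.
#' @return A list: `best` (named hyperparameters + mean CV AUROC) and
#'   `table` (one row per grid point with its CV AUROC).
#' @export
grid_search_cv <- function(x, labels, config = forest_config(), seed = 1L) {
  x <- as.data.frame(x)
  y <- as_binary_labels(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (nrow(x) < config$folds)
    stop("fewer rows than folds", call. = FALSE)
  fold <- cv_folds(y, config$folds, seed)
  grid <- expand.grid(mtry = config$mtry_grid, ntree = config$ntree_grid,
                      max_node = config$max_node_grid)
  grid$cv_auroc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(config$folds), function(k) {
      tr <- fold != k
      fit <- train_forest(x[tr, , drop = FALSE], y[tr],
                          mtry = grid$mtry[g], ntree = grid$ntree[g],
                          max_node = grid$max_node[g],
                          seed = seed + 1000L * k + g)
      auroc(predict(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    grid$cv_auroc[g] <- mean(aucs)
  }
  ord <- order(-grid$cv_auroc, grid$ntree, grid$max_node, grid$mtry)
  best <- grid[ord[1L], ]
  list(best = list(mtry = best$mtry, ntree = best$ntree,
                   max_node = best$max_node, cv_auroc = best$cv_auroc),
       table = grid)
}

#' Normalized Gini feature importance
#'
#' Total decrease in Gini impurity attributed to each feature across all
#' splits of all trees, normalized so the top feature scores 100, in
#' descending order.
#'
#' @param model A `trained_forest`.
#' @return Data frame with columns `feature`, `importance`.
#' @export
forest_importance <- function(model) {
  stopifnot(inherits(model, "trained_forest"))
  imp <- randomForest::importance(model$forest, type = 2)[, 1]
  imp <- 100 * imp / max(imp)
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) form with average ranks for ties:
#' the probability that a random pathogenic variant outscores a random
#' benign one, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more pathogenic).
#' @param labels `"B"`/`"P"` vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == "P"); n_neg <- sum(y == "B")
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == "P"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated: thresholds descend through the unique score values
#' (tied scores enter together) and the curve accumulates
#' `precision * delta-recall`.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == "P")
  if (n_pos == 0L || sum(y == "B") == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- y[ord] == "P"
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(s, fromLast = TRUE)  # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate scores against labels
#' @inheritParams auroc
#' @return A list with `auroc` and `auprc`.
#' @export
evaluate_scores <- function(scores, labels) {
  list(auroc = auroc(scores, labels), auprc = auprc(scores, labels))
}

FOREST_ARCHIVE_VERSION <- 1L

#' Save / load a trained forest
#'
#' Single-file versioned archive (trees, imputation medians, feature
#' registry, config, seed). Loading refuses archives written with a
#' different format version; prediction refuses registry mismatches.
#'
#' @param model A `trained_forest`.
#' @param path Archive path.
#' @return `save_forest` the path; `load_forest` the `trained_forest`.
#' @export
save_forest <- function(model, path) {
  stopifnot(inherits(model, "trained_forest"))
  saveRDS(list(version = FOREST_ARCHIVE_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$version, FOREST_ARCHIVE_VERSION))
    stop("unsupported model archive version: ", arch$version, call. = FALSE)
  arch$model
}
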