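# Per-class Random Forest classifiers trained for balanced accuracy.
# Tree growth is delegated to the randomForest package; the balancing
# mechanism (per-tree balanced bootstrap), the balanced-accuracy
# objective, the smallest-forest grid-search selection and the
# vote-threshold prediction are defined here.
#
# The namespace import guarantees predict.randomForest is registered
# even in sessions that only load serialized models and never train.
#' @importFrom randomForest randomForest
NULL

.LABELS <- c("benign", "deleterious")

.as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .LABELS)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  factor(labels, levels = .LABELS)
}

#' Balanced accuracy
#'
#' Mean of sensitivity (recall on deleterious) and specificity (recall
#' on benign): equal weight to both classes regardless of prevalence.
#'
#' @param true_labels,predicted_labels equal-length vectors over
#'   `"benign"`/`"deleterious"`.
#' @return numeric in \[0,1\]. Errors on empty input or when a class is
#'   absent from `true_labels`.
#' @export
balanced_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  tr <- .as_label_factor(true_labels)
  pr <- .as_label_factor(predicted_labels)
  if (any(table(tr) == 0L))
    stop("both classes must be present in the true labels")
  sens <- mean(pr[tr == "deleterious"] == "deleterious")
  spec <- mean(pr[tr == "benign"] == "benign")
  (sens + spec) / 2
}

#' Train a per-class Random Forest
#'
#' Grows `n_trees` CART trees (Gini impurity) with
#' `n_features_per_split` candidate features per split. Under the default
#' `"balanced"` strategy each tree's bootstrap draws equal numbers from
#' both classes (with replacement), realizing the balanced-accuracy
#' training objective; `"plain"` uses the ordinary bootstrap. Training is
#' reproducible for a fixed seed. The decision threshold defaults to a
#' strict majority of trees and is carried in the model.
#'
#' @param x numeric data.frame/matrix, columns = one class schema.
#' @param labels vector over `"benign"`/`"deleterious"`, >=2 of each.
#' @param n_trees number of trees (>= 1).
#' @param n_features_per_split candidate features per split (<= ncol(x)).
#' @param seed RNG seed for reproducible growth.
#' @param balance `"balanced"` (default) or `"plain"` bootstrap.
#' @param model_class optional class tag stored in the model.
#' @param max_nodes optional maximum terminal nodes per tree (tree-size
#'   limit; default unlimited).
#' @param threshold votes needed for a deleterious call (default strict
#'   majority).
#' @return object of class `ForestModel`.
#' @export
train_forest <- function(x, labels, n_trees, n_features_per_split,
                         seed = 1L, balance = c("balanced", "plain"),
                         model_class = NA_character_, max_nodes = NULL,
                         threshold = NULL) {
  balance <- match.arg(balance)
  x <- as.data.frame(x)
  y <- .as_label_factor(labels)
  tab <- table(y)
  if (any(tab < 2L))
    stop("need at least 2 examples of each class (got ",
         paste(tab, collapse = "/"), ")")
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (n_features_per_split > ncol(x))
    stop("n_features_per_split exceeds the schema width")
  set.seed(as.integer(seed))
  args <- list(x = x, y = y, ntree = n_trees,
               mtry = as.integer(n_features_per_split), replace = TRUE)
  if (balance == "balanced") {
    k <- min(tab)
    args$strata <- y
    args$sampsize <- c(k, k)
  }
  if (!is.null(max_nodes)) args$maxnodes <- as.integer(max_nodes)
  rf <- do.call(randomForest::randomForest, args)
  thr <- if (is.null(threshold)) n_trees %/% 2L + 1L else as.integer(threshold)
  if (thr < 1L || thr > n_trees) stop("threshold must lie in [1, n_trees]")
  structure(list(model_class = model_class, rf = rf, n_trees = n_trees,
                 n_features_per_split = as.integer(n_features_per_split),
                 schema = colnames(x),
                 schema_version = feature_schema_version(),
                 training_seed = as.integer(seed), balance = balance,
                 threshold = thr, version = "1"),
            class = "ForestModel")
}

#' @export
print.ForestModel <- function(x, ...) {
  cat(sprintf("ForestModel (%s): %d trees, mtry %d, threshold %d, seed %d\n",
              x$model_class, x$n_trees, x$n_features_per_split,
              x$threshold, x$training_seed))
  invisible(x)
}

#' Tree-vote prediction
#'
#' Every tree votes; the output reports how many trees are suggestive of
#' deleteriousness (no probability or confidence score is produced). The
#' label is `deleterious` iff the vote count reaches the model's
#' threshold.
#'
#' @param object a `ForestModel`.
#' @param newdata data.frame/matrix matching the model schema.
#' @param ... unused.
#' @return data.frame with `label`, `votes_deleterious`, `n_trees`.
#' @export
predict.ForestModel <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!identical(colnames(newdata), object$schema))
    stop("feature schema mismatch: model was trained on (",
         paste(object$schema, collapse = ", "), ")")
  votes <- predict(object$rf, newdata, type = "vote", norm.votes = FALSE)
  vd <- as.integer(votes[, "deleterious"])
  data.frame(label = ifelse(vd >= object$threshold, "deleterious", "benign"),
             votes_deleterious = vd, n_trees = object$n_trees,
             stringsAsFactors = FALSE)
}

#' Stratified cross-validation folds
#'
#' Deterministic fold assignment given a seed; each class is shuffled and
#' dealt cyclically so folds stay class-balanced.
#'
#' @param labels label vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold ids (1..k) per observation.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  y <- .as_label_factor(labels)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid search with smallest-forest selection
#'
#' Evaluates k-fold cross-validated balanced accuracy at every
#' (tree count, features-per-split) grid point and selects the SMALLEST
#' forest — fewest trees, ties broken by fewer features — whose score
#' lies within `tolerance_pp` percentage points of the grid maximum
#' (default 0.12 pp), trading forest size against accuracy. Per-fold
#' training uses seed `seed + fold`, identical across grid points, so a
#' fold-by-fold recomputation reproduces the table exactly.
#'
#' @param x numeric feature data.frame.
#' @param labels labels over `"benign"`/`"deleterious"`.
#' @param tree_grid,feature_grid candidate tree counts / mtry values.
#' @param k_folds folds (default 5, stratified).
#' @param seed RNG seed for folds and training.
#' @param tolerance_pp allowed balanced-accuracy loss, percentage points.
#' @param balance bootstrap strategy, see [train_forest()].
#' @return list with `n_trees`, `n_features_per_split`, `score_table`
#'   (n_trees, n_features_per_split, balanced_accuracy), `best_score`,
#'   `chosen_score`.
#' @export
grid_search_forest <- function(x, labels, tree_grid, feature_grid,
                               k_folds = 5L, seed = 1L, tolerance_pp = 0.12,
                               balance = "balanced") {
  if (length(tree_grid) == 0L || length(feature_grid) == 0L)
    stop("empty grid")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  x <- as.data.frame(x)
  y <- .as_label_factor(labels)
  fold <- make_stratified_folds(y, k_folds, seed)
  for (f in seq_len(k_folds))
    if (any(table(y[fold == f]) == 0L))
      stop("fold ", f, " contains a single class")
  grid <- expand.grid(n_trees = sort(as.integer(tree_grid)),
                      n_features_per_split = sort(as.integer(feature_grid)))
  grid$balanced_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    scores <- vapply(seq_len(k_folds), function(f) {
      tr <- fold != f
      m <- train_forest(x[tr, , drop = FALSE], y[tr],
                        n_trees = grid$n_trees[g],
                        n_features_per_split = grid$n_features_per_split[g],
                        seed = seed + f, balance = balance)
      p <- predict(m, x[!tr, , drop = FALSE])
      balanced_accuracy(y[!tr], p$label)
    }, numeric(1))
    grid$balanced_accuracy[g] <- mean(scores)
  }
  sel <- select_forest_size(grid, tolerance_pp)
  c(sel, list(score_table = grid))
}

#' Smallest-forest selection from a score table
#'
#' Given cross-validated balanced accuracies per (n_trees,
#' n_features_per_split) grid point, returns the smallest forest (fewest
#' trees, ties broken by fewer features per split) within `tolerance_pp`
#' percentage points of the maximum. With `tolerance_pp = 0` this is the
#' exact argmax.
#'
#' @param score_table data.frame with columns n_trees,
#'   n_features_per_split, balanced_accuracy.
#' @param tolerance_pp allowed loss in percentage points (default 0.12).
#' @return list with `n_trees`, `n_features_per_split`, `best_score`,
#'   `chosen_score`.
#' @export
select_forest_size <- function(score_table, tolerance_pp = 0.12) {
  best <- max(score_table$balanced_accuracy)
  ok <- score_table[score_table$balanced_accuracy >= best - tolerance_pp / 100,
                    , drop = FALSE]
  ok <- ok[order(ok$n_trees, ok$n_features_per_split), , drop = FALSE]
  list(n_trees = ok$n_trees[1L],
       n_features_per_split = ok$n_features_per_split[1L],
       best_score = best, chosen_score = ok$balanced_accuracy[1L])
}

#' Save / load a forest model
#'
#' Serialized ensemble with metadata (class, tree count, schema version,
#' training seed, format version).
#'
#' @param model a `ForestModel`.
#' @param path file path.
#' @export
save_forest <- function(model, path) {
  stopifnot(inherits(model, "ForestModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_forest
#' @return `load_forest` returns the `ForestModel`.
#' @export
load_forest <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ForestModel")) stop("not a ForestModel file: ", path)
  m
}
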