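# Balanced accuracy, balanced-bootstrap forests, grid search and votes.

# two-class Gaussian blobs separated by d pooled SDs in each of k features
make_blobs <- function(n_benign, n_deleterious, d = 3, k = 5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_benign * k), ncol = k),
             matrix(rnorm(n_deleterious * k, mean = d), ncol = k))
  colnames(x) <- paste0("f", seq_len(k))
  list(x = as.data.frame(x),
       y = rep(c("benign", "deleterious"), c(n_benign, n_deleterious)))
}

test_that("balanced accuracy equals (sens+spec)/2 on forced confusion tables", {
  # perfect and constant predictors
  y <- rep(c("benign", "deleterious"), c(5, 5))
  expect_equal(balanced_accuracy(y, y), 1.0)
  expect_equal(balanced_accuracy(y, rep("deleterious", 10)), 0.5)
  # TP=8 FN=2 TN=6 FP=4 -> (0.8 + 0.6)/2 = 0.7
  truth <- rep(c("deleterious", "benign"), c(10, 10))
  pred <- c(rep("deleterious", 8), rep("benign", 2),
            rep("benign", 6), rep("deleterious", 4))
  expect_equal(balanced_accuracy(truth, pred), 0.7)
})

test_that("balanced accuracy input contract", {
  expect_error(balanced_accuracy(character(0), character(0)), "empty")
  expect_error(balanced_accuracy(rep("benign", 4), rep("benign", 4)),
               "both classes")
  expect_error(balanced_accuracy(c("benign", "deleterious"), "benign"),
               "length")
  expect_error(balanced_accuracy(c("benign", "bad"), c("benign", "benign")),
               "unknown label")
})

test_that("balanced accuracy is symmetric under label swap", {
  set.seed(41)
  swap <- function(v) ifelse(v == "benign", "deleterious", "benign")
  for (i in 1:20) {
    truth <- sample(c("benign", "deleterious"), 30, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pred <- sample(c("benign", "deleterious"), 30, replace = TRUE)
    expect_equal(balanced_accuracy(truth, pred),
                 balanced_accuracy(swap(truth), swap(pred)))
  }
})

test_that("training is reproducible and validates its inputs", {
  b <- make_blobs(40, 40, d = 2, k = 3, seed = 42)
  m1 <- train_forest(b$x, b$y, 30, 2, seed = 5)
  m2 <- train_forest(b$x, b$y, 30, 2, seed = 5)
  probe <- make_blobs(20, 20, d = 2, k = 3, seed = 43)$x
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_error(train_forest(b$x, rep("benign", 80), 10, 2), "each class")
  expect_error(train_forest(b$x, b$y, 10, 99), "schema width")
  expect_error(train_forest(b$x, b$y, 10, 2, threshold = 11), "threshold")
})

test_that("a separable problem is learned perfectly in-sample", {
  b <- make_blobs(60, 60, d = 6, k = 2, seed = 44)
  m <- train_forest(b$x, b$y, 50, 1, seed = 1)
  p <- predict(m, b$x)
  expect_equal(balanced_accuracy(b$y, p$label), 1.0)
})

test_that("votes are conserved and equal the per-tree oracle", {
  b <- make_blobs(30, 30, d = 2, k = 3, seed = 45)
  m <- train_forest(b$x, b$y, 5, 2, seed = 9)
  probe <- make_blobs(10, 10, d = 2, k = 3, seed = 46)$x
  p <- predict(m, probe)
  expect_true(all(p$votes_deleterious >= 0 & p$votes_deleterious <= 5))
  expect_true(all(p$n_trees == 5L))
  # per-tree oracle: query each tree individually and sum its votes
  ind <- predict(m$rf, probe, predict.all = TRUE)$individual
  expect_equal(unname(rowSums(ind == "deleterious")),
               p$votes_deleterious)
  # threshold semantics: strict majority
  expect_equal(p$label, ifelse(p$votes_deleterious >= 3,
                               "deleterious", "benign"))
  expect_error(predict(m, probe[, c(2, 1, 3)]), "schema mismatch")
})

test_that("smallest-forest selection rule on forced score tables", {
  tab <- data.frame(
    n_trees = c(100L, 300L), n_features_per_split = c(3L, 3L),
    balanced_accuracy = c(0.949, 0.950))
  # 0.1 pp loss is within the 0.12 pp budget: take the small forest
  s <- select_forest_size(tab, tolerance_pp = 0.12)
  expect_equal(s$n_trees, 100L)
  expect_equal(s$chosen_score, 0.949)
  # zero tolerance picks the argmax
  s <- select_forest_size(tab, tolerance_pp = 0)
  expect_equal(s$n_trees, 300L)
  # tie on trees broken by fewer features
  tab2 <- data.frame(n_trees = c(50L, 50L), n_features_per_split = c(5L, 2L),
                     balanced_accuracy = c(0.96, 0.96))
  expect_equal(select_forest_size(tab2, 0)$n_features_per_split, 2L)
})

test_that("grid search scores match an independent fold-by-fold oracle", {
  b <- make_blobs(60, 60, d = 1.5, k = 4, seed = 47)
  gs <- grid_search_forest(b$x, b$y, tree_grid = c(10, 25),
                           feature_grid = c(1, 2), k_folds = 3, seed = 3)
  # recompute the whole table from scratch with the documented protocol
  fold <- make_stratified_folds(b$y, 3, seed = 3)
  for (r in seq_len(nrow(gs$score_table))) {
    scores <- vapply(1:3, function(f) {
      tr <- fold != f
      m <- train_forest(b$x[tr, ], b$y[tr],
                        n_trees = gs$score_table$n_trees[r],
                        n_features_per_split =
                          gs$score_table$n_features_per_split[r],
                        seed = 3 + f)
      balanced_accuracy(b$y[!tr], predict(m, b$x[!tr, ])$label)
    }, numeric(1))
    expect_equal(gs$score_table$balanced_accuracy[r], mean(scores))
  }
  expect_equal(c(gs$n_trees, gs$n_features_per_split),
               unlist(select_forest_size(gs$score_table, 0.12)[1:2]),
               ignore_attr = TRUE)
  expect_error(grid_search_forest(b$x, b$y, integer(0), 1), "empty grid")
  expect_error(grid_search_forest(b$x, b$y, 10, 1, k_folds = 1), "k_folds")
})

test_that("balanced bootstrap closes the sensitivity/specificity gap under 100:1 imbalance", {
  set.seed(48)
  b <- make_blobs(2000, 20, d = 3, k = 5, seed = 48)
  probe <- make_blobs(400, 400, d = 3, k = 5, seed = 49)
  gap <- function(balance) {
    m <- train_forest(b$x, b$y, 80, 2, seed = 4, balance = balance)
    p <- predict(m, probe$x)
    sens <- mean(p$label[probe$y == "deleterious"] == "deleterious")
    spec <- mean(p$label[probe$y == "benign"] == "benign")
    abs(sens - spec)
  }
  g_bal <- gap("balanced"); g_plain <- gap("plain")
  expect_lt(g_bal, 0.15)
  expect_gt(g_plain, g_bal)
})

test_that("forest serialization round-trips predictions", {
  b <- make_blobs(30, 30, d = 2, k = 3, seed = 50)
  m <- train_forest(b$x, b$y, 20, 2, seed = 1, model_class = "without_aae")
  path <- withr::local_tempfile(fileext = ".rds")
  save_forest(m, path)
  m2 <- load_forest(path)
  expect_equal(m2$model_class, "without_aae")
  expect_identical(predict(m2, b$x), predict(m, b$x))
})
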