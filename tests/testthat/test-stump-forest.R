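feature_rows <- function(m) {
  colnames(m) <- c("tm5_len", "tm5_tilt", "tm6_outward")
  m
}

# linearly separated two-class toy data on all three features
separated_data <- function(n_per_class, gap = 6, seed = 5) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(3 * n_per_class, mean = gap), ncol = 3L),
               matrix(stats::rnorm(3 * n_per_class, mean = -gap), ncol = 3L))
    list(x = feature_rows(x),
         y = rep(c("GS", "GIO"), each = n_per_class))
  })
}

test_that("stumps separate separable data and fits are seed-reproducible", {
  d <- separated_data(30)
  m1 <- fit_stump_forest(d$x, d$y, seed = 123L)
  m2 <- fit_stump_forest(d$x, d$y, seed = 123L)
  expect_identical(m1$trees, m2$trees)
  expect_length(m1$trees, 15L)
  expect_true(all(vapply(m1$trees, function(t) t$feature_index %in% 1:3, TRUE)))
  expect_identical(predict(m1, d$x), d$y)
  expect_gte(mean(predict(m1, d$x) == d$y), 0.95)
  m3 <- fit_stump_forest(d$x, d$y, seed = 124L)
  expect_false(identical(m1$trees, m3$trees))
  expect_error(fit_stump_forest(d$x, rep("GS", nrow(d$x))), "single class")
})

test_that("class weights balance the 24:74 composition inside the leaves", {
  # weighted totals are equal (24 * 74 == 74 * 24): a stump threshold placed
  # outside the data range must not let the abundant class dominate the leaf
  w <- c(GS = 74, GIO = 24)
  labels <- rep(c("GS", "GIO"), times = c(24, 74))
  expect_equal(sum(w[labels][labels == "GS"]), sum(w[labels][labels == "GIO"]))
  tree <- gcoupler:::fit_stump(rep(1, 98), labels, unname(w[labels]), 1L)
  expect_identical(tree$left_class, "GIO")   # exact tie falls to Gi/o
})

test_that("prediction scores are the fraction of stumps voting Gs", {
  unanimous <- structure(list(trees = replicate(15, list(
    feature_index = 1L, threshold = 0, left_class = "GS", right_class = "GS"),
    simplify = FALSE)), class = "stump_forest")
  x <- feature_rows(matrix(0, 1, 3))
  expect_equal(predict_score(unanimous, x), 1.0)
  split8 <- structure(list(trees = c(
    replicate(8, list(feature_index = 1L, threshold = 1, left_class = "GS",
                      right_class = "GS"), simplify = FALSE),
    replicate(7, list(feature_index = 1L, threshold = 1, left_class = "GIO",
                      right_class = "GIO"), simplify = FALSE))),
    class = "stump_forest")
  expect_equal(predict_score(split8, x), 8 / 15)
  expect_identical(predict(split8, x), "GS")
  expect_error(predict_score(structure(list(trees = list()),
                                       class = "stump_forest"), x),
               "not a fitted")
})

test_that("stratified folds preserve the class ratio within one member", {
  labels <- rep(c("GS", "GIO"), times = c(24, 74))
  fold <- stratified_folds(labels, k = 10L, seed = 3L)
  tab <- table(fold, labels)
  expect_true(all(tab[, "GS"] %in% 2:3))
  expect_true(all(tab[, "GIO"] %in% 7:8))
  expect_equal(sum(tab), 98)
  fold2 <- stratified_folds(rep(c("GS", "GIO"), each = 4), k = 2L, seed = 1L)
  expect_equal(unname(as.vector(table(fold2))), c(4L, 4L))
  expect_warning(
    f <- stratified_folds(rep(c("GS", "GIO"), each = 5), k = 10L, seed = 1L),
    "reducing k")
  expect_equal(max(f), 5L)
  expect_error(stratified_folds(labels, k = 1L), ">= 2")
})

test_that("cross-validation tests every row exactly once and scores sanely", {
  d <- separated_data(20, gap = 4)
  cv <- stratified_kfold_cv(d$x, d$y, k = 5L, seed = 9L)
  expect_equal(cv$k, 5L)
  expect_equal(sum(cv$pooled$confusion), 40)
  expect_gte(cv$pooled$accuracy, 0.95)
  expect_gte(cv$pooled$auc, 0.95)
})

test_that("metrics match their closed forms", {
  # 49 correct of 54 with the 20:34 class split
  y <- rep(c("GS", "GIO"), times = c(20, 34))
  pred <- y
  pred[c(1, 2, 3, 21, 22)] <- ifelse(y[c(1, 2, 3, 21, 22)] == "GS", "GIO", "GS")
  m <- compute_metrics(y, pred)
  expect_equal(m$accuracy, 49 / 54)
  expect_equal(round(100 * m$accuracy, 2), 90.74)
  # TP=3 TN=4 FP=1 FN=0 -> MCC = 12/sqrt(240)
  y2 <- c(rep("GS", 3), rep("GIO", 5))
  p2 <- c(rep("GS", 3), "GS", rep("GIO", 4))
  m2 <- compute_metrics(y2, p2)
  expect_equal(m2$mcc, 12 / sqrt(240), tolerance = 1e-12)
  expect_equal(m2$f1, 2 * 3 / (2 * 3 + 1 + 0))
  perfect <- compute_metrics(y2, y2, as.numeric(y2 == "GS"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$mcc, 1)
  expect_error(compute_metrics(y2, p2[-1]), "differ")
  # metrics recomputed from the emitted confusion matrix agree exactly
  cm <- m$confusion
  expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(m$f1, 2 * cm[1, 1] / (2 * cm[1, 1] + cm[2, 1] + cm[1, 2]))
})

test_that("AUC equals the rank-statistic oracle", {
  skip_if_not_installed("pROC")
  withr::local_seed(17)
  for (rep in 1:10) {
    y <- sample(rep(c("GS", "GIO"), times = c(12, 20)))
    s <- stats::rnorm(32) + (y == "GS")
    ours <- compute_metrics(y, ifelse(s > 0.5, "GS", "GIO"), s)$auc
    oracle <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = c("GIO", "GS"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U handles midrank ties and exact small samples", {
  tie <- mann_whitney_u(1, 1)
  expect_equal(tie$U, 0.5)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)       # exact: 2/20 arrangements as extreme
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})
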