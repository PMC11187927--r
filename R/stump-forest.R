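#' Bagged class-weighted decision-stump forest
#'
#' The coupling classifier is a deliberately constrained random forest: 15
#' depth-1 trees (stumps), each trained on a bootstrap bag of
#' `ceiling(0.7 n)` rows drawn with replacement and splitting on a single
#' randomly chosen feature at the class-weighted-Gini-optimal threshold.
#' Class weights (Gs 74, Gi/o 24 by default — inverse to the 24:74 training
#' composition, so the weighted class totals balance) enter both the
#' impurity and the leaf majority votes. The severe constraints guard
#' against overfitting the small training set.
#'
#' @param features data.frame/matrix of (standardized) feature rows with
#'   columns `tm5_len`, `tm5_tilt`, `tm6_outward`.
#' @param labels character vector of `"GS"` / `"GIO"`, one per row.
#' @param n_estimators number of stumps (default 15).
#' @param class_weights named vector of per-class sample weights.
#' @param bagging_fraction bag size as a fraction of n (default 0.7).
#' @param seed integer RNG seed; the fit is bit-reproducible per seed.
#' @return A `stump_forest` with a `trees` list, each tree
#'   `list(feature_index, threshold, left_class, right_class)` (left =
#'   feature value <= threshold).
#' @export
fit_stump_forest <- function(features, labels, n_estimators = 15L,
                             class_weights = c(GS = 74, GIO = 24),
                             bagging_fraction = 0.7, seed = 2784L) {
  x <- feature_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("cannot fit: training labels contain a single class")
  }
  w <- unname(class_weights[labels])
  n <- nrow(x)
  bag_size <- ceiling(bagging_fraction * n)
  trees <- withr::with_seed(seed, lapply(seq_len(n_estimators), function(i) {
    bag <- sample.int(n, bag_size, replace = TRUE)
    j <- sample.int(ncol(x), 1L)
    fit_stump(x[bag, j], labels[bag], w[bag], j)
  }))
  structure(list(trees = trees, n_estimators = n_estimators,
                 max_depth = 1L, max_features = 1L,
                 class_weights = class_weights,
                 bagging_fraction = bagging_fraction, seed = seed,
                 feature_names = colnames(x)),
            class = "stump_forest")
}

# weighted-Gini-optimal threshold on one feature; candidates are midpoints
# between consecutive distinct values
fit_stump <- function(v, labels, w, feature_index) {
  ord <- order(v)
  v <- v[ord]; labels <- labels[ord]; w <- w[ord]
  is_gs <- labels == "GS"
  tot_gs <- sum(w[is_gs]); tot_gi <- sum(w[!is_gs])
  leaf <- function(gs, gi) if (gs > gi) "GS" else "GIO"
  if (tot_gs == 0 || tot_gi == 0) {
    # single-class bag: degenerate stump voting that class everywhere
    cls <- leaf(tot_gs, tot_gi)
    return(list(feature_index = feature_index, threshold = -Inf,
                left_class = cls, right_class = cls))
  }
  cum_gs <- cumsum(w * is_gs); cum_gi <- cumsum(w * !is_gs)
  # split after position i is valid only between distinct values
  valid <- which(diff(v) > 0)
  if (length(valid) == 0L) {
    cls <- leaf(tot_gs, tot_gi)
    return(list(feature_index = feature_index, threshold = -Inf,
                left_class = cls, right_class = cls))
  }
  wl <- cum_gs[valid] + cum_gi[valid]
  wr <- (tot_gs + tot_gi) - wl
  gini_l <- 1 - (cum_gs[valid] / wl)^2 - (cum_gi[valid] / wl)^2
  gini_r <- 1 - ((tot_gs - cum_gs[valid]) / wr)^2 -
                ((tot_gi - cum_gi[valid]) / wr)^2
  impurity <- (wl * gini_l + wr * gini_r) / (tot_gs + tot_gi)
  best <- valid[which.min(impurity)]
  list(feature_index = feature_index,
       threshold = (v[best] + v[best + 1L]) / 2,
       left_class = leaf(cum_gs[best], cum_gi[best]),
       right_class = leaf(tot_gs - cum_gs[best], tot_gi - cum_gi[best]))
}

#' @rdname fit_stump_forest
#' @param model a fitted `stump_forest`.
#' @return `predict_score`: per-row fraction of stumps voting Gs, in
#'   `[0, 1]`; `predict.stump_forest`: `"GS"`/`"GIO"` labels (score > 0.5 is
#'   Gs; a tied vote falls to the majority Gi/o class).
#' @export
predict_score <- function(model, features) {
  if (!inherits(model, "stump_forest") || length(model$trees) == 0L) {
    stop("model is not a fitted stump forest")
  }
  x <- feature_matrix(features)
  votes <- vapply(model$trees, function(tr) {
    ifelse(x[, tr$feature_index] <= tr$threshold,
           tr$left_class, tr$right_class) == "GS"
  }, logical(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  unname(rowMeans(votes))
}

#' @rdname fit_stump_forest
#' @param object a fitted `stump_forest`.
#' @param ... unused.
#' @export
predict.stump_forest <- function(object, features, ...) {
  ifelse(predict_score(object, features) > 0.5, "GS", "GIO")
}

#' Stratified k-fold assignment and cross-validation
#'
#' `stratified_folds` assigns rows to k folds preserving the class ratio
#' within one member per class; `stratified_kfold_cv` runs the full
#' standardize + stump-forest pipeline with training-fold-only
#' standardization and returns per-fold and pooled metrics. If the rarer
#' class has fewer than k members, k is reduced to that count with a
#' warning.
#'
#' @param labels class labels.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return `stratified_folds`: integer fold id per row.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 2784L) {
  if (k < 2L) stop("k must be >= 2")
  n_min <- min(table(labels))
  if (n_min < k) {
    warning("reducing k from ", k, " to ", n_min,
            " (rarer class has only ", n_min, " members)")
    k <- n_min
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' @rdname stratified_folds
#' @param features raw feature rows (`tm5_len`, `tm5_tilt`, `tm6_outward`).
#' @param ... passed to [fit_stump_forest()].
#' @return `stratified_kfold_cv`: list with `fold_metrics` (per-fold
#'   data.frame), `pooled` ([compute_metrics()] over all held-out
#'   predictions), `k`.
#' @export
stratified_kfold_cv <- function(features, labels, k = 10L, seed = 2784L, ...) {
  x <- feature_matrix(features)
  labels <- as.character(labels)
  fold <- stratified_folds(labels, k, seed)
  k <- max(fold)
  pred <- character(length(labels)); score <- numeric(length(labels))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    std <- fit_standardization(x[!test, , drop = FALSE])
    z_tr <- standardize(x[!test, , drop = FALSE], std)
    z_te <- standardize(x[test, , drop = FALSE], std)
    model <- fit_stump_forest(z_tr, labels[!test], seed = seed + f, ...)
    score[test] <- predict_score(model, z_te)
    pred[test] <- ifelse(score[test] > 0.5, "GS", "GIO")
    m <- compute_metrics(labels[test], pred[test], score[test])
    per_fold[[f]] <- data.frame(fold = f, accuracy = m$accuracy, f1 = m$f1,
                                mcc = m$mcc)
  }
  list(fold_metrics = do.call(rbind, per_fold),
       pooled = compute_metrics(labels, pred, score), k = k)
}

#' Binary classification metrics with Gs as the positive class
#'
#' Accuracy, F1 (Gs positive), AUC (Mann-Whitney rank statistic on the Gs
#' score, midrank ties) and the Matthews correlation coefficient, plus the
#' 2x2 confusion matrix (rows = truth, columns = prediction).
#'
#' @param y_true,y_pred character vectors of `"GS"` / `"GIO"`.
#' @param y_score optional numeric Gs score for AUC.
#' @return `classifier_metrics`: list `accuracy`, `f1`, `auc`, `mcc`,
#'   `confusion`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  lev <- c("GS", "GIO")
  if (!all(lev %in% y_true)) stop("both classes must appear in y_true")
  cm <- table(factor(y_true, lev), factor(y_pred, lev))
  tp <- cm["GS", "GS"]; fn <- cm["GS", "GIO"]
  fp <- cm["GIO", "GS"]; tn <- cm["GIO", "GIO"]
  n <- sum(cm)
  f1_den <- 2 * tp + fp + fn
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  auc <- if (is.null(y_score)) NA_real_ else {
    pos <- y_score[y_true == "GS"]; neg <- y_score[y_true == "GIO"]
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }
  structure(list(
    accuracy = (tp + tn) / n,
    f1 = if (f1_den == 0) NA_real_ else 2 * tp / f1_den,
    auc = auc,
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    confusion = matrix(c(tp, fn, fp, tn), 2L, 2L,
                       dimnames = list(true = lev, predicted = lev))),
    class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  F1 %.4f  AUC %s  MCC %.4f\n", x$accuracy, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)), x$mcc))
  print(x$confusion)
  invisible(x)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison as used for the per-feature Gs vs Gi/o
#' group contrasts: U with midrank ties, exact p for small untied samples
#' and the tie-corrected normal approximation otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param group_a,group_b numeric vectors.
#' @return list `U` (statistic for `group_a`), `p` (two-sided).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = NULL,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
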