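# Classifier, evaluation metrics and leakage-safe cross-validation.
#
# The classifier sits behind a small fit/score-probability contract so the
# pipeline can be exercised with any plug-in; the production default is the
# in-package gradient-boosted tree ensemble (src/gbdt.cpp) with the
# hyperparameters max_depth = 15, num_leaves = 50, n_estimators = 1000.

#' Classifier configuration
#'
#' @param max_depth maximum tree depth (default 15).
#' @param num_leaves maximum leaves per tree (default 50).
#' @param n_estimators number of boosting rounds (default 1000).
#' @param learning_rate shrinkage per round (default 0.1, the conventional
#'   GBDT default; the source work does not report one).
#' @param min_data_in_leaf minimum samples per leaf (default 20, the
#'   conventional GBDT default).
#' @param seed RNG seed recorded with the model. The default booster is
#'   deterministic (no subsampling), so the seed only matters for plug-in
#'   backends that use randomness.
#' @param backend `"gbdt"` for the built-in booster, or a
#'   `list(fit = function(x, y, config), predict_prob = function(fit, x))`
#'   plug-in.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(max_depth = 15L, num_leaves = 50L,
                              n_estimators = 1000L, learning_rate = 0.1,
                              min_data_in_leaf = 20L, seed = 1L,
                              backend = "gbdt") {
  stopifnot(max_depth >= 1, num_leaves >= 2, n_estimators >= 1,
            learning_rate > 0, min_data_in_leaf >= 1)
  structure(
    list(max_depth = as.integer(max_depth), num_leaves = as.integer(num_leaves),
         n_estimators = as.integer(n_estimators),
         learning_rate = learning_rate,
         min_data_in_leaf = as.integer(min_data_in_leaf),
         seed = as.integer(seed), backend = backend),
    class = "classifier_config"
  )
}

.as_feature_matrix <- function(x) {
  if (inherits(x, "feature_table")) x <- x$features
  as.matrix(x)
}

#' Train the classifier
#'
#' @param x `feature_table`, data.frame or numeric matrix of features.
#' @param labels binary 0/1 vector, one per row; both classes required.
#' @param config a [classifier_config()].
#' @return object of class `hotwave_model` supporting [predict_prob()].
#' @export
train_classifier <- function(x, labels, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  xm <- .as_feature_matrix(x)
  if (length(labels) != nrow(xm)) stop("labels/rows mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    stop("need at least 2 samples of each class", call. = FALSE)
  }
  if (is.list(config$backend)) {
    fit <- config$backend$fit(xm, labels, config)
    backend <- config$backend
  } else {
    fit <- gbdt_train_cpp(xm, as.numeric(labels), config$n_estimators,
                          config$learning_rate, config$max_depth,
                          config$num_leaves, config$min_data_in_leaf)
    backend <- "gbdt"
  }
  structure(list(fit = fit, backend = backend, config = config,
                 feature_names = colnames(xm)),
            class = "hotwave_model")
}

#' Score class-1 probabilities on new rows
#'
#' @param model a `hotwave_model`.
#' @param x features with the same columns as at training time.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "hotwave_model"))
  xm <- .as_feature_matrix(x)
  fn <- model$feature_names
  if (!is.null(fn)) {
    missing <- setdiff(fn, colnames(xm))
    if (length(missing)) {
      stop("schema error: scoring table lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    xm <- xm[, fn, drop = FALSE]
  }
  if (is.list(model$backend)) {
    return(model$backend$predict_prob(model$fit, xm))
  }
  gbdt_predict_cpp(model$fit, xm)
}

#' Confusion counts at a probability threshold
#'
#' A sample is predicted positive when its score is greater than or equal to
#' the threshold (a score of exactly 0.5 is a positive call at the default).
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores, same length.
#' @param threshold decision threshold (default 0.5).
#' @return list with integer counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (!length(labels)) stop("empty input", call. = FALSE)
  if (length(labels) != length(scores)) {
    stop("labels/scores length mismatch", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1L & labels == 1),
       fp = sum(pred == 1L & labels == 0),
       tn = sum(pred == 0L & labels == 0),
       fn = sum(pred == 0L & labels == 1))
}

# Degenerate denominators (no predicted positives, single-class truth, zero
# MCC denominator) return 0 with a warning rather than NaN.
.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' F1 = 2*SEN*PRE/(SEN+PRE), accuracy (TP+TN)/total, and the Matthews
#' correlation coefficient.
#'
#' @param cc confusion counts as returned by [confusion()].
#' @return named numeric vector `(sen, spe, pre, f1, acc, mcc)`.
#' @export
metrics_from_confusion <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  sen <- .safe_ratio(tp, tp + fn, "SEN")
  spe <- .safe_ratio(tn, tn + fp, "SPE")
  pre <- .safe_ratio(tp, tp + fp, "PRE")
  f1 <- .safe_ratio(2 * sen * pre, sen + pre, "F1")
  acc <- .safe_ratio(tp + tn, tp + fp + tn + fn, "ACC")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); returning 0", call. = FALSE)
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  c(sen = sen, spe = spe, pre = pre, f1 = f1, acc = acc, mcc = mcc)
}

#' Rank-based ROC AUC
#'
#' Computed as the normalised Mann-Whitney U statistic from midranks, so tied
#' scores are credited 0.5.
#'
#' @param labels binary 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels/scores length mismatch", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present for AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric set from labels and scores
#'
#' @inheritParams confusion
#' @return named numeric vector `(sen, spe, pre, f1, acc, mcc, auc)`.
#' @export
metric_set <- function(labels, scores, threshold = 0.5) {
  c(metrics_from_confusion(confusion(labels, scores, threshold)),
    auc = roc_auc(labels, scores))
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

.balance_table <- function(ft, method, seed, k = 5L) {
  switch(method,
    none = ft,
    smote = smote_balance(ft, k = k, seed = seed),
    random = random_oversample(ft, seed = seed),
    stop("unknown balance method '", method, "'", call. = FALSE)
  )
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class. Class balancing (`"smote"`, `"random"` or
#' `"none"`) is applied to the training portion of each fold only, so no
#' synthetic point ever leaks information from held-out rows. Metrics are
#' computed on the pooled out-of-fold predictions of each repeat; repeats use
#' derived seeds `seed + r - 1`.
#'
#' @param ft labelled `feature_table`.
#' @param folds number of folds (default 10); must not exceed the minority
#'   class size.
#' @param repeats number of repetitions (default 1).
#' @param seed base RNG seed.
#' @param balance balancing method applied inside training folds.
#' @param config a [classifier_config()].
#' @param smote_k SMOTE neighbour count.
#' @return object of class `cv_result`: `per_repeat` (matrix of metric sets,
#'   one row per repeat), `mean` (column means), plus the call parameters.
#' @export
cross_validate <- function(ft, folds = 10L, repeats = 1L, seed = 1L,
                           balance = c("smote", "random", "none"),
                           config = classifier_config(), smote_k = 5L) {
  stopifnot(inherits(ft, "feature_table"))
  balance <- match.arg(balance)
  labels <- ft$labels
  if (is.null(labels)) stop("table must carry labels", call. = FALSE)
  n_min <- min(table(labels))
  if (folds < 2L || folds > n_min) {
    stop("cross_validate: fold count must be in [2, minority class size = ",
         n_min, "]", call. = FALSE)
  }
  x <- ft$features
  per_repeat <- NULL
  for (r in seq_len(repeats)) {
    rseed <- seed + r - 1L
    fold_of <- stratified_folds(labels, folds, rseed)
    scores <- rep(NA_real_, length(labels))
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      train_ft <- feature_table(x[tr, , drop = FALSE], labels = labels[tr],
                                stage = "selected")
      train_ft <- .balance_table(train_ft, balance, seed = rseed + 1000L * f,
                                 k = smote_k)
      model <- train_classifier(train_ft$features, train_ft$labels, config)
      scores[!tr] <- predict_prob(model, x[!tr, , drop = FALSE])
    }
    stopifnot(!anyNA(scores)) # every row scored exactly once per repeat
    per_repeat <- rbind(per_repeat, metric_set(labels, scores))
  }
  rownames(per_repeat) <- paste0("repeat", seq_len(repeats))
  structure(
    list(per_repeat = per_repeat, mean = colMeans(per_repeat),
         folds = folds, repeats = repeats, seed = seed, balance = balance),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d repeat(s), balance=%s\n",
              x$folds, x$repeats, x$balance))
  print(round(x$mean, 4))
  invisible(x)
}
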