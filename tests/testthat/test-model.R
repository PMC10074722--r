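test_that("confusion tallies at the >= 0.5 boundary and matches brute force", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(cc, list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  expect_equal(confusion(c(1, 0), c(0.5, 0.5)),
               list(tp = 1L, fp = 1L, tn = 0L, fn = 0L)) # 0.5 is positive
  expect_error(confusion(numeric(0), numeric(0)), "empty")

  labels <- with_seed2(31, rbinom(100, 1, 0.4))
  scores <- with_seed2(32, runif(100))
  cc <- confusion(labels, scores)
  tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in 1:100) {
    pred <- scores[i] >= 0.5
    if (pred && labels[i] == 1) tally["tp"] <- tally["tp"] + 1
    if (pred && labels[i] == 0) tally["fp"] <- tally["fp"] + 1
    if (!pred && labels[i] == 0) tally["tn"] <- tally["tn"] + 1
    if (!pred && labels[i] == 1) tally["fn"] <- tally["fn"] + 1
  }
  expect_equal(unlist(cc), tally[c("tp", "fp", "tn", "fn")],
               ignore_attr = TRUE)
  expect_equal(sum(unlist(cc)), 100)
})

test_that("metrics_from_confusion implements the defining formulas", {
  m <- metrics_from_confusion(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(unname(m["sen"]), 0.6)
  expect_equal(unname(m["spe"]), 0.8)
  expect_equal(unname(m["pre"]), 0.75)
  expect_equal(unname(m["acc"]), 0.7)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(m["mcc"]), 10 / sqrt(600))

  perfect <- metrics_from_confusion(list(tp = 5, fp = 0, tn = 7, fn = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1, 1))

  allneg <- suppressWarnings(
    metrics_from_confusion(list(tp = 0, fp = 0, tn = 6, fn = 4)))
  expect_equal(unname(allneg["sen"]), 0)
  expect_equal(unname(allneg["spe"]), 1)
  w <- capture_warnings(metrics_from_confusion(list(tp = 0, fp = 0,
                                                    tn = 6, fn = 4)))
  expect_true(any(grepl("undefined", w)))

  # identities hold on random confusion tables
  for (i in 1:50) {
    cc <- as.list(with_seed2(400 + i, rpois(4, 10) + 1))
    names(cc) <- c("tp", "fp", "tn", "fn")
    m <- metrics_from_confusion(cc)
    with(cc, {
      expect_equal(unname(m["sen"]), tp / (tp + fn))
      expect_equal(unname(m["spe"]), tn / (tn + fp))
      expect_equal(unname(m["pre"]), tp / (tp + fp))
      expect_equal(unname(m["f1"]),
                   2 * m[["sen"]] * m[["pre"]] / (m[["sen"]] + m[["pre"]]))
      expect_equal(unname(m["acc"]), (tp + tn) / (tp + fp + tn + fn))
      expect_equal(unname(m["mcc"]),
                   (tp * tn - fp * fn) /
                     sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
    })
    expect_true(m[["mcc"]] >= -1 && m[["mcc"]] <= 1)
  }
})

test_that("roc_auc is the tie-aware rank statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.7, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  labels <- with_seed2(61, rbinom(200, 1, 0.3))
  scores <- with_seed2(62, round(runif(200), 2)) # rounded to force ties
  expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores))
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(labels, exp(3 * scores)), roc_auc(labels, scores))
  expect_equal(roc_auc(labels, rank(scores, ties.method = "average")),
               roc_auc(labels, scores))
})

test_that("the boosted-tree backend is deterministic and fits separable data", {
  ft <- toy_table(n = 200, p = 3, seed = 71, effect = 4)
  cfg <- classifier_config(n_estimators = 50, num_leaves = 8, max_depth = 5)
  model <- train_classifier(ft, ft$labels, cfg)
  p1 <- predict_prob(model, ft)
  expect_equal(unname(metric_set(ft$labels, p1)["acc"]), 1.0)
  model2 <- train_classifier(ft, ft$labels, cfg)
  expect_identical(p1, predict_prob(model2, ft))

  # scoring a table lacking a training column is a schema error
  expect_error(predict_prob(model, ft$features[, 1:2]), "lacks column")
  expect_error(train_classifier(ft, rep(1, 200), cfg), "each class")

  # plug-in backend honours the fit/score contract
  stump <- list(
    fit = function(x, y, config) mean(y),
    predict_prob = function(fit, x) rep(fit, nrow(x))
  )
  m <- train_classifier(ft, ft$labels, classifier_config(backend = stump))
  expect_equal(predict_prob(m, ft), rep(0.5, 200))
})

test_that("classifier_config defaults match the reference hyperparameters", {
  cfg <- classifier_config()
  expect_identical(cfg$max_depth, 15L)
  expect_identical(cfg$num_leaves, 50L)
  expect_identical(cfg$n_estimators, 1000L)
  expect_error(classifier_config(num_leaves = 1), "num_leaves")
})

test_that("cross_validate is stratified, leakage-safe and deterministic", {
  # 2-sigma shifts on three of five columns: Bayes AUC ~ pnorm(2*sqrt(3)/sqrt(2))
  ft <- with_seed2(81, {
    labels <- rep(c(1, 0), 100)
    x <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    x[labels == 1, 1:3] <- x[labels == 1, 1:3] + 2
    feature_table(as.data.frame(x), labels = labels, stage = "selected")
  })
  cfg <- classifier_config(n_estimators = 100, num_leaves = 8, max_depth = 5)
  cv <- cross_validate(ft, folds = 10, seed = 1, balance = "smote",
                       config = cfg)
  expect_gt(cv$mean[["auc"]], 0.95) # strongly separated data

  cv2 <- cross_validate(ft, folds = 10, repeats = 2, seed = 1,
                        balance = "smote", config = cfg)
  cv3 <- cross_validate(ft, folds = 10, repeats = 2, seed = 1,
                        balance = "smote", config = cfg)
  expect_identical(cv2$per_repeat, cv3$per_repeat)
  expect_equal(nrow(cv2$per_repeat), 2L)

  expect_error(cross_validate(ft, folds = 150), "fold count")

  # permuted labels: AUC hovers around chance
  null_ft <- with_seed2(99, {
    f <- ft
    f$labels <- sample(f$labels)
    f
  })
  null_cv <- suppressWarnings(
    cross_validate(null_ft, folds = 10, repeats = 10, seed = 7,
                   balance = "smote", config = cfg))
  expect_lt(abs(mean(null_cv$per_repeat[, "auc"]) - 0.5), 0.1)
})
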