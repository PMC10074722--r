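# Two-step feature selection: mRMR ranking (MID scheme with plug-in mutual
# information on mean +/- sigma three-bin discretization) followed by
# sequential forward selection under cross-validated AUC.

#' Three-bin discretization at mean +/- sigma
#'
#' Bins a numeric feature for mutual-information estimation: values at or
#' below mu - sigma map to 0, values at or above mu + sigma map to 2, the
#' rest map to 1 (sigma is the population standard deviation). Constant
#' vectors map to all-1.
#'
#' @param values numeric vector, >= 2 samples.
#' @return integer vector of categories in \{0, 1, 2\}.
#' @export
discretize_feature <- function(values) {
  if (length(values) < 2L) stop("need >= 2 samples", call. = FALSE)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) return(rep(1L, length(values)))
  out <- rep(1L, length(values))
  out[values <= mu - sigma] <- 0L
  out[values >= mu + sigma] <- 2L
  out
}

#' Plug-in mutual information of two discrete vectors
#'
#' Empirical joint-frequency estimate, in nats:
#' \eqn{\sum_{x,y} p(x,y) \ln[p(x,y) / (p(x) p(y))]}.
#'
#' @param x,y equal-length category vectors.
#' @return non-negative scalar.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  max(0, sum(terms[joint > 0]))
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy-maximum-relevance ordering (MID difference
#' scheme): the first feature maximizes relevance I(f; y); each subsequent
#' feature maximizes I(f; y) minus the mean mutual information with the
#' already-selected set. Ties break deterministically toward the
#' lexicographically smallest feature name. Features are discretized with
#' [discretize_feature()] before estimation.
#'
#' @param ft labelled `feature_table` with >= 2 feature columns.
#' @return character vector: all feature names in mRMR order.
#' @export
mrmr_rank <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  labels <- ft$labels
  if (is.null(labels) || length(unique(labels)) < 2L) {
    stop("mrmr_rank requires labels from both classes", call. = FALSE)
  }
  feats <- names(ft$features)
  disc <- lapply(ft$features, discretize_feature)
  relevance <- vapply(disc, mutual_information, numeric(1), y = labels)

  pair_mi <- matrix(NA_real_, length(feats), length(feats),
                    dimnames = list(feats, feats))
  get_mi <- function(a, b) {
    if (is.na(pair_mi[a, b])) {
      m <- mutual_information(disc[[a]], disc[[b]])
      pair_mi[a, b] <<- pair_mi[b, a] <<- m
    }
    pair_mi[a, b]
  }

  pick_best <- function(cand, score) {
    best <- max(score)
    ties <- cand[score >= best - 1e-12]
    sort(ties)[1L]
  }

  remaining <- feats
  ranked <- character(0)
  redundancy_sum <- setNames(numeric(length(feats)), feats)
  while (length(remaining)) {
    if (!length(ranked)) {
      score <- relevance[remaining]
    } else {
      last <- ranked[length(ranked)]
      for (f in remaining) {
        redundancy_sum[f] <- redundancy_sum[f] + get_mi(f, last)
      }
      score <- relevance[remaining] - redundancy_sum[remaining] / length(ranked)
    }
    chosen <- pick_best(remaining, score)
    ranked <- c(ranked, chosen)
    remaining <- setdiff(remaining, chosen)
  }
  ranked
}

#' Sequential forward selection over an mRMR-ranked feature list
#'
#' Walks the ranking in order; each feature is tentatively added and the
#' candidate subset is scored by mean stratified k-fold cross-validated AUC
#' (with balancing applied inside training folds). The feature is kept iff
#' the score strictly improves on the incumbent best. Fold assignment is
#' fixed by the seed, so all candidate subsets are compared on identical
#' folds.
#'
#' @param ranked ordered feature names (typically from [mrmr_rank()]).
#' @param ft labelled `feature_table` containing at least those columns.
#' @param folds CV folds (default 10).
#' @param config [classifier_config()] used for the wrapper fits; the default
#'   here is a lighter booster (200 trees, 8 leaves, depth 5) than the final
#'   model, since the wrapper performs O(p) cross-validated fits.
#' @param seed RNG seed for folds and balancing.
#' @param balance balancing method inside training folds (default SMOTE).
#' @param smote_k SMOTE neighbour count.
#' @return object of class `selection_result`: `ranked`, `chosen`,
#'   `cv_scores` (AUC per evaluated candidate subset, named by the tested
#'   feature), `best_size`, `best_score`.
#' @export
sfs_select <- function(ranked, ft, folds = 10L,
                       config = classifier_config(n_estimators = 200L,
                                                  num_leaves = 8L,
                                                  max_depth = 5L),
                       seed = 1L, balance = "smote", smote_k = 5L) {
  stopifnot(inherits(ft, "feature_table"))
  if (!length(ranked)) stop("ranked feature list is empty", call. = FALSE)
  missing <- setdiff(ranked, names(ft$features))
  if (length(missing)) {
    stop("ranked features absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- ft$labels
  chosen <- character(0)
  best <- -Inf
  cv_scores <- numeric(0)
  for (f in ranked) {
    cand <- c(chosen, f)
    sub <- feature_table(ft$features[cand], labels = labels,
                         stage = "selected")
    auc <- cross_validate(sub, folds = folds, repeats = 1L, seed = seed,
                          balance = balance, config = config,
                          smote_k = smote_k)$mean[["auc"]]
    cv_scores[f] <- auc
    if (auc > best) {
      best <- auc
      chosen <- cand
    }
  }
  structure(
    list(ranked = ranked, chosen = chosen, cv_scores = cv_scores,
         best_size = length(chosen), best_score = best),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features chosen of %d ranked (CV AUC %.3f)\n",
              x$best_size, length(x$ranked), x$best_score))
  cat("  ", paste(x$chosen, collapse = ", "), "\n")
  invisible(x)
}
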