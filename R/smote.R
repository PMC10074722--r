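# Class balancing: SMOTE k-nearest-neighbour interpolation and the
# random-repeat oversampling baseline. Both act only on the minority class;
# majority rows are never touched, and original rows are retained first.

.minority_majority <- function(labels) {
  if (is.null(labels)) stop("table must carry labels", call. = FALSE)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) {
    stop("both classes must be present to balance", call. = FALSE)
  }
  minority <- as.integer(names(tab)[which.min(tab)])
  list(minority = minority, n_min = min(tab), n_maj = max(tab))
}

#' SMOTE class balancing
#'
#' Synthesises minority-class samples until the classes are balanced. Each
#' synthetic point interpolates between a randomly chosen minority sample X
#' and one of its k nearest minority neighbours X_n (Euclidean distance):
#' `X_new = X + u * (X_n - X)` with `u ~ Uniform(0, 1)`, so every synthetic
#' point lies on the segment joining two original minority points. Synthetic
#' rows are appended after the originals with the minority label; residue
#' metadata is dropped from the output since synthetic rows correspond to no
#' physical residue.
#'
#' @param ft labelled `feature_table`.
#' @param k number of nearest neighbours (default 5); must be smaller than
#'   the minority class size.
#' @param seed RNG seed (default 114 for reproducibility).
#' @param runif_fn uniform generator, exposed as a test hook; defaults to
#'   [stats::runif()].
#' @return balanced `feature_table` with equal class counts.
#' @export
smote_balance <- function(ft, k = 5L, seed = 114L, runif_fn = stats::runif) {
  stopifnot(inherits(ft, "feature_table"))
  mm <- .minority_majority(ft$labels)
  if (mm$n_min <= k) {
    stop("minority class size (", mm$n_min, ") must exceed k = ", k,
         "; use a smaller k", call. = FALSE)
  }
  n_new <- mm$n_maj - mm$n_min
  x <- as.matrix(ft$features)
  min_idx <- which(ft$labels == mm$minority)
  xm <- x[min_idx, , drop = FALSE]
  dmat <- as.matrix(stats::dist(xm))
  diag(dmat) <- Inf
  # k nearest minority neighbours per minority row, deterministic tie-break
  # by row index via order()'s stable sort
  nn <- do.call(rbind, lapply(seq_len(nrow(dmat)),
                              function(i) order(dmat[i, ])[seq_len(k)]))
  synth <- matrix(NA_real_, nrow = n_new, ncol = ncol(x),
                  dimnames = list(NULL, colnames(x)))
  with_seed(seed, {
    for (i in seq_len(n_new)) {
      b <- sample.int(nrow(xm), 1L)
      nb <- nn[b, sample.int(k, 1L)]
      u <- runif_fn(1L)
      synth[i, ] <- xm[b, ] + u * (xm[nb, ] - xm[b, ])
    }
  })
  feats <- rbind(ft$features, as.data.frame(synth))
  rownames(feats) <- NULL
  labels <- c(ft$labels, rep(mm$minority, n_new))
  feature_table(feats, labels = labels, meta = NULL, stage = ft$stage)
}

#' Random-repeat oversampling baseline
#'
#' Duplicates uniformly sampled minority rows until the class counts are
#' equal. An already balanced table is returned unchanged.
#'
#' @param ft labelled `feature_table`.
#' @param seed RNG seed.
#' @return balanced `feature_table`.
#' @export
random_oversample <- function(ft, seed = 114L) {
  stopifnot(inherits(ft, "feature_table"))
  mm <- .minority_majority(ft$labels)
  n_new <- mm$n_maj - mm$n_min
  if (n_new == 0L) return(ft)
  min_idx <- which(ft$labels == mm$minority)
  picks <- with_seed(seed, sample(min_idx, n_new, replace = TRUE))
  feats <- rbind(ft$features, ft$features[picks, , drop = FALSE])
  rownames(feats) <- NULL
  labels <- c(ft$labels, rep(mm$minority, n_new))
  feature_table(feats, labels = labels, meta = NULL, stage = ft$stage)
}
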