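# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as literal loop-based evaluations of the defining
# formulas, sharing no code with the package implementation.

# One filter-bank analysis step: explicit convolution-decimation sums with
# the Haar analysis filter pair, periodized by repeating the last sample on
# odd lengths.
oracle_haar_step <- function(s) {
  if (length(s) %% 2 == 1) s <- c(s, s[length(s)])
  g <- c(1, 1) / sqrt(2)
  h <- c(1, -1) / sqrt(2)
  half <- length(s) / 2
  a <- d <- numeric(half)
  for (n in seq_len(half)) {
    for (tap in 1:2) {
      k <- 2 * (n - 1) + tap
      a[n] <- a[n] + s[k] * g[tap]
      d[n] <- d[n] + s[k] * h[tap]
    }
  }
  list(approx = a, detail = d)
}

oracle_dwt <- function(s, levels = 3) {
  approx <- detail <- vector("list", levels)
  cur <- s
  for (j in seq_len(levels)) {
    st <- oracle_haar_step(cur)
    approx[[j]] <- st$approx
    detail[[j]] <- st$detail
    cur <- st$approx
  }
  list(approx = approx, detail = detail)
}

oracle_wpt_nodes <- function(s) {
  nodes <- list(s)
  for (lev in 1:3) {
    out <- list()
    for (nd in nodes) {
      st <- oracle_haar_step(nd)
      out <- c(out, list(st$approx), list(st$detail))
    }
    nodes <- out
  }
  nodes
}

# Per-formula entropy oracles (natural log, E[0] = 0 conventions).
oracle_entropies <- function(s) {
  sh <- le <- 0
  for (v in s) {
    if (v != 0) {
      sh <- sh - v^2 * log(v^2)
      le <- le + log(v^2)
    }
  }
  th <- sum(abs(s) > 0.2)
  sure <- length(s) - sum(abs(s) <= 3) + sum(pmin(s^2, 9))
  nrm <- sum(abs(s)^1.3)
  c(shannon = sh, log_energy = le, threshold = th, sure = sure, norm = nrm)
}

# Brute-force check that `pt` lies on the segment between two rows of `xm`
# (all-pairs search, coordinate-wise parameter consistency).
oracle_on_segment <- function(pt, xm, tol = 1e-8) {
  n <- nrow(xm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- xm[i, ]; b <- xm[j, ]
      dir <- b - a
      if (all(abs(dir) < tol)) {
        if (all(abs(pt - a) < tol)) return(TRUE)
        next
      }
      k <- which.max(abs(dir))
      t <- (pt[k] - a[k]) / dir[k]
      if (t < -tol || t > 1 + tol) next
      if (all(abs(a + t * dir - pt) < tol)) return(TRUE)
    }
  }
  FALSE
}

# Plug-in mutual information from an explicit joint count loop.
oracle_mi <- function(x, y) {
  n <- length(x)
  xs <- unique(x); ys <- unique(y)
  mi <- 0
  for (xv in xs) {
    for (yv in ys) {
      pxy <- sum(x == xv & y == yv) / n
      if (pxy > 0) {
        mi <- mi + pxy * log(pxy / ((sum(x == xv) / n) * (sum(y == yv) / n)))
      }
    }
  }
  mi
}

# Exhaustive evaluation of the greedy mRMR (MID) criterion on discretized
# columns: at each step score every remaining feature from scratch.
oracle_mrmr <- function(disc, labels) {
  feats <- names(disc)
  ranked <- character(0)
  while (length(feats)) {
    scores <- vapply(feats, function(f) {
      rel <- oracle_mi(disc[[f]], labels)
      if (!length(ranked)) return(rel)
      red <- mean(vapply(ranked, function(s) oracle_mi(disc[[f]], disc[[s]]),
                         numeric(1)))
      rel - red
    }, numeric(1))
    best <- max(scores)
    pick <- sort(feats[scores >= best - 1e-12])[1]
    ranked <- c(ranked, pick)
    feats <- setdiff(feats, pick)
  }
  ranked
}

# O(n^2) pairwise AUC with 0.5 credit for ties.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Named 43-vector of traditional features with distinct sentinel values.
sentinel_traditional <- function() {
  cols <- traditional_columns()
  v <- seq_along(cols) + 0.5
  v[cols == "hbond_count"] <- 3
  stats::setNames(v, cols)
}

# Small labelled feature table with plain Gaussian columns (no schema).
toy_table <- function(n = 40, p = 3, seed = 1, effect = 0) {
  with_seed2(seed, {
    labels <- rep(c(1, 0), length.out = n)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    if (effect != 0) x[labels == 1, 1] <- x[labels == 1, 1] + effect
    feature_table(as.data.frame(x), labels = labels, stage = "selected")
  })
}

# local-seed helper for test fixtures (tests must not disturb global RNG)
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
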