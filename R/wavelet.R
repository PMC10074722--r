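# Multilevel Haar (db1) analysis of short signals.
#
# Analysis filters: low-pass g = (1, 1)/sqrt(2), high-pass h = (1, -1)/sqrt(2)
# (orthonormal, so energy is conserved exactly for power-of-two lengths).
# Boundary rule: odd-length inputs are extended by repeating the last sample
# before convolution-decimation, which keeps three decomposition levels
# well-defined for the length-6 secondary-structure signal (6 -> 3 -> 2 -> 1).

.check_signal <- function(x) {
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("signal must be finite numeric", call. = FALSE)
  }
}

#' One Haar analysis step
#'
#' Splits a signal into approximation (low-pass) and detail (high-pass)
#' coefficients by convolution with the Haar filter pair followed by dyadic
#' decimation. Odd-length signals are first extended by repeating the last
#' sample.
#'
#' @param x numeric signal, length >= 1.
#' @return list with components `approx` and `detail`, each of length
#'   `ceiling(length(x)/2)`.
#' @export
#' @examples
#' haar_analysis_step(c(3, 1, 2, 4))  # approx 4/sqrt(2), 6/sqrt(2)
haar_analysis_step <- function(x) {
  .check_signal(x)
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  odd <- x[seq(1L, length(x), by = 2L)]
  even <- x[seq(2L, length(x), by = 2L)]
  s2 <- sqrt(2)
  list(approx = (odd + even) / s2, detail = (odd - even) / s2)
}

#' Multilevel Haar discrete wavelet transform
#'
#' Applies [haar_analysis_step()] recursively to the approximation branch.
#' The level count is honoured even when the approximation shrinks to a
#' single sample (length-1 signals are extended by the boundary rule).
#'
#' @param x numeric signal, length >= 2.
#' @param levels number of decomposition levels (default 3).
#' @return object of class `wavelet_decomposition` with fields `levels`,
#'   `approx` (list of per-level approximation coefficient vectors),
#'   `detail` (per-level detail vectors) and `input_length`.
#' @export
dwt_multilevel <- function(x, levels = 3L) {
  .check_signal(x)
  if (length(x) < 2L) stop("signal length must be >= 2", call. = FALSE)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    st <- haar_analysis_step(cur)
    approx[[j]] <- st$approx
    detail[[j]] <- st$detail
    cur <- st$approx
  }
  structure(
    list(levels = as.integer(levels), approx = approx, detail = detail,
         input_length = length(x)),
    class = "wavelet_decomposition"
  )
}

#' Level-3 wavelet packet transform
#'
#' Unlike the DWT, both the low- and high-pass branches are split at every
#' level, producing 2^3 = 8 terminal sub-bands after three levels. Nodes are
#' returned in natural (filter-order) indexing: at each split the low-pass
#' child precedes the high-pass child.
#'
#' @param x numeric signal, length >= 2.
#' @return object of class `wpt_terminal_nodes`: list with `nodes` (list of 8
#'   coefficient vectors) and `input_length`.
#' @export
wpt_level3 <- function(x) {
  .check_signal(x)
  if (length(x) < 2L) stop("signal length must be >= 2", call. = FALSE)
  nodes <- list(x)
  for (lev in 1:3) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      st <- haar_analysis_step(nodes[[i]])
      nxt[[2L * i - 1L]] <- st$approx
      nxt[[2L * i]] <- st$detail
    }
    nodes <- nxt
  }
  structure(list(nodes = nodes, input_length = length(x)),
            class = "wpt_terminal_nodes")
}

energy <- function(v) sum(v^2)

#' Energy percentages of a multilevel DWT
#'
#' `ea[j]` is the percentage of the level-`j` decomposition energy carried by
#' the approximation branch: 100 * E(approx_j) / (E(approx_j) + sum of
#' E(detail_i) for i <= j). `ed` is the detail share at the deepest level,
#' 100 - ea[levels], so `ea[3] + ed = 100` holds by construction. `ea_std`
#' is the population (divisor-n) standard deviation of the three `ea` values.
#'
#' @param decomp a `wavelet_decomposition` with 3 levels.
#' @return list with `ea` (length 3), `ea_mean`, `ea_std`, `ed`.
#' @export
dwt_energy_summary <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  if (decomp$levels != 3L) stop("expected a 3-level decomposition", call. = FALSE)
  det_e <- vapply(decomp$detail, energy, numeric(1))
  app_e <- vapply(decomp$approx, energy, numeric(1))
  total3 <- app_e[3] + sum(det_e)
  if (total3 <= 0) {
    stop("all-zero decomposition: energy percentages undefined", call. = FALSE)
  }
  ea <- vapply(1:3, function(j) {
    100 * app_e[j] / (app_e[j] + sum(det_e[seq_len(j)]))
  }, numeric(1))
  list(
    ea = ea,
    ea_mean = mean(ea),
    ea_std = sqrt(mean((ea - mean(ea))^2)),
    ed = 100 - ea[3]
  )
}

#' Energy summary of wavelet packet terminal nodes
#'
#' @param wpt a `wpt_terminal_nodes` object.
#' @return list with `absolute` (8 node energies), `relative` (8 percentages
#'   summing to 100) and `total` (absolute energy sum).
#' @export
wpt_energy_summary <- function(wpt) {
  stopifnot(inherits(wpt, "wpt_terminal_nodes"))
  absolute <- vapply(wpt$nodes, energy, numeric(1))
  total <- sum(absolute)
  if (total <= 0) {
    stop("all-zero nodes: relative energies undefined", call. = FALSE)
  }
  list(absolute = absolute, relative = 100 * absolute / total, total = total)
}

#' Shannon wavelet entropy
#'
#' \eqn{E_s(s) = -\sum_i s_i^2 \ln(s_i^2)}; zero coefficients contribute 0
#' (additive-cost convention, so the entropy of the zero vector is 0).
#'
#' @param s numeric coefficient vector.
#' @return scalar entropy (natural log).
#' @export
shannon_entropy <- function(s) {
  if (length(s) && any(!is.finite(s))) stop("non-finite input", call. = FALSE)
  s2 <- s[s != 0]^2
  if (!length(s2)) return(0)
  -sum(s2 * log(s2))
}

#' Log-energy wavelet entropy
#'
#' \eqn{E_l(s) = \sum_i \ln(s_i^2)}, with zero coefficients contributing 0
#' so the cost of the zero vector is 0.
#'
#' @param s numeric coefficient vector.
#' @return scalar entropy (natural log).
#' @export
log_energy_entropy <- function(s) {
  if (length(s) && any(!is.finite(s))) stop("non-finite input", call. = FALSE)
  s2 <- s[s != 0]^2
  if (!length(s2)) return(0)
  sum(log(s2))
}

#' Threshold, SURE and norm wavelet entropies
#'
#' Threshold entropy counts coefficients exceeding 0.2 in magnitude. SURE
#' entropy uses threshold 3: `n - #(|s_i| <= 3) + sum(min(s_i^2, 9))`. Norm
#' entropy is `sum(|s_i|^1.3)`. All three are additive costs that vanish on
#' the zero vector and are invariant under zero-padding.
#'
#' @param s numeric coefficient vector.
#' @return list with components `threshold`, `sure`, `norm`.
#' @export
threshold_sure_norm_entropies <- function(s) {
  if (length(s) && any(!is.finite(s))) stop("non-finite input", call. = FALSE)
  n <- length(s)
  eps <- 3
  list(
    threshold = sum(abs(s) > 0.2),
    sure = n - sum(abs(s) <= eps) + sum(pmin(s^2, eps^2)),
    norm = sum(abs(s)^1.3)
  )
}

#' All five wavelet entropies in fixed order
#'
#' @param s numeric coefficient vector.
#' @return named numeric vector `(shannon, log_energy, threshold, sure,
#'   norm)`.
#' @export
entropy_vector <- function(s) {
  tsn <- threshold_sure_norm_entropies(s)
  c(shannon = shannon_entropy(s),
    log_energy = log_energy_entropy(s),
    threshold = tsn$threshold,
    sure = tsn$sure,
    norm = tsn$norm)
}
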