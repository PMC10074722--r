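# Synthetic data: labelled residue tables with the traditional 43-column
# schema and a Gaussian class-conditional structure, plus small fixture
# signals for wavelet unit tests. The defaults mirror the benchmark training
# set (101 hot spots vs 170 non-hot spots).

#' Simulation configuration
#'
#' @param n_pos,n_neg class sizes (defaults 101 and 170, the benchmark
#'   training-set counts).
#' @param informative_columns traditional columns receiving a class mean
#'   shift; default is the relative-change solvent-accessibility block
#'   (`asa_delta`), the block most associated with hot spots.
#' @param effect_size mean shift in the positive class, in units of
#'   `noise_sigma` (default 2).
#' @param noise_sigma Gaussian noise standard deviation (default 1).
#' @param seed RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_pos = 101L, n_neg = 170L,
                              informative_columns = traditional_columns("asa_delta"),
                              effect_size = 2.0, noise_sigma = 1.0,
                              seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, noise_sigma > 0)
  bad <- setdiff(informative_columns, traditional_columns())
  if (length(bad)) {
    stop("unknown informative column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         informative_columns = informative_columns,
         effect_size = effect_size, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a traditional-stage residue feature table
#'
#' Non-informative columns are Normal(0, sigma^2) in both classes;
#' informative columns receive an additional `effect_size * sigma` mean shift
#' in the positive class. The hydrogen-bond column is rounded to a
#' non-negative integer. Binding free-energy changes are drawn so that
#' [label_from_ddg()] reproduces the generating class exactly: positives get
#' `1 + Exp(1)` kcal/mol, negatives `Uniform(-1, 0.999)`. Deterministic for
#' a given seed.
#'
#' @param config a [simulation_config()].
#' @return labelled `feature_table` at stage `"traditional"` with `ddg` (and
#'   placeholder identity columns) in its metadata.
#' @export
simulate_table <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_pos + config$n_neg
  cls <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  cols <- traditional_columns()
  with_seed(config$seed, {
    x <- matrix(stats::rnorm(n * length(cols), sd = config$noise_sigma),
                nrow = n, dimnames = list(NULL, cols))
    shift <- config$effect_size * config$noise_sigma
    for (cn in config$informative_columns) {
      x[cls == 1L, cn] <- x[cls == 1L, cn] + shift
    }
    x[, "hbond_count"] <- pmax(0, round(abs(x[, "hbond_count"]) * 3))
    ddg <- ifelse(cls == 1L, 1 + stats::rexp(n), stats::runif(n, -1, 0.999))
  })
  meta <- data.frame(
    pdb_id = sprintf("S%03d", seq_len(n)),
    chain = "A",
    position = seq_len(n),
    wt_residue = "A",
    ddg = ddg,
    stringsAsFactors = FALSE
  )
  feature_table(as.data.frame(x), labels = cls, meta = meta,
                stage = "traditional")
}

#' Fixture signals for wavelet tests
#'
#' @param length signal length, 6 or 8 (the two group lengths the pipeline
#'   uses).
#' @param kind `"constant"`, `"alternating"` or `"random"`.
#' @param seed RNG seed (random kind only).
#' @param constant value used by the constant kind (default 1).
#' @return numeric vector of the requested length.
#' @export
simulate_signal <- function(length = 8L, kind = c("constant", "alternating",
                                                  "random"),
                            seed = 1L, constant = 1) {
  kind <- match.arg(kind)
  if (!length %in% c(6L, 8L)) {
    stop("unsupported signal length (use 6 or 8)", call. = FALSE)
  }
  switch(kind,
    constant = rep(constant, length),
    alternating = rep_len(c(1, -1), length),
    random = with_seed(seed, stats::rnorm(length))
  )
}
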