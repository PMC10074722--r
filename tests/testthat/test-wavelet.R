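test_that("haar_analysis_step matches the filter-bank definition", {
  expect_equal(haar_analysis_step(c(1, 1)),
               list(approx = sqrt(2), detail = 0))
  expect_equal(haar_analysis_step(c(1, -1)),
               list(approx = 0, detail = sqrt(2)))
  expect_equal(haar_analysis_step(c(3, 1, 2, 4)),
               list(approx = c(4, 6) / sqrt(2), detail = c(2, -2) / sqrt(2)))
  # odd length: last sample repeated before decimation
  expect_equal(haar_analysis_step(c(1, 3, 5)),
               list(approx = c(4, 10) / sqrt(2), detail = c(-2, 0) / sqrt(2)))
  expect_error(haar_analysis_step(numeric(0)), "empty")
})

test_that("dwt_multilevel has dyadic coefficient counts and kills constants", {
  d <- dwt_multilevel(rep(3, 8))
  expect_equal(d$approx[[3]], 3 * 2 * sqrt(2))
  for (j in 1:3) expect_equal(d$detail[[j]], rep(0, length(d$detail[[j]])))
  lens <- vapply(1:3, function(j) c(length(d$approx[[j]]),
                                    length(d$detail[[j]])), integer(2))
  expect_equal(lens, matrix(c(4L, 4L, 2L, 2L, 1L, 1L), 2))
  # length-6 secondary-structure signals still decompose three levels
  d6 <- dwt_multilevel(1:6)
  expect_equal(vapply(d6$approx, length, integer(1)), c(3L, 2L, 1L))
  expect_error(dwt_multilevel(1:8, levels = 0), "levels")
  expect_error(dwt_multilevel(3), ">= 2")
})

test_that("DWT conserves energy and matches the brute-force filter sums", {
  for (i in 1:100) {
    s <- with_seed2(1000 + i, rnorm(8))
    d <- dwt_multilevel(s)
    total <- sum(d$approx[[3]]^2) + sum(unlist(d$detail)^2)
    expect_lt(abs(total - sum(s^2)), 1e-9)
  }
  for (i in 1:50) {
    s <- with_seed2(2000 + i, rnorm(8))
    d <- dwt_multilevel(s)
    o <- oracle_dwt(s)
    for (j in 1:3) {
      expect_equal(d$approx[[j]], o$approx[[j]], tolerance = 1e-12)
      expect_equal(d$detail[[j]], o$detail[[j]], tolerance = 1e-12)
    }
  }
})

test_that("level-3 WPT yields 8 nodes, conserves energy, matches the oracle", {
  w <- wpt_level3(rep(2, 8))
  expect_length(w$nodes, 8L)
  expect_equal(w$nodes[[1]], 2 * 2 * sqrt(2))
  expect_equal(unlist(w$nodes[2:8]), rep(0, 7))
  for (i in 1:100) {
    s <- with_seed2(3000 + i, rnorm(8))
    w <- wpt_level3(s)
    expect_length(w$nodes, 8L)
    expect_lt(abs(sum(unlist(w$nodes)^2) - sum(s^2)), 1e-9)
    expect_equal(unlist(w$nodes), unlist(oracle_wpt_nodes(s)),
                 tolerance = 1e-12)
  }
  expect_error(wpt_level3(numeric(0)), "empty")
})

test_that("dwt_energy_summary implements the per-level approximation share", {
  es <- dwt_energy_summary(dwt_multilevel(rep(5, 8)))
  expect_equal(es$ea, rep(100, 3))
  expect_equal(es$ea_mean, 100)
  expect_equal(es$ea_std, 0)
  expect_equal(es$ed, 0)

  alt <- dwt_energy_summary(dwt_multilevel(rep_len(c(1, -1), 8)))
  expect_equal(alt$ea, rep(0, 3))
  expect_equal(alt$ed, 100)

  for (i in 1:20) {
    s <- with_seed2(4000 + i, rnorm(8))
    d <- dwt_multilevel(s)
    es <- dwt_energy_summary(d)
    expect_equal(es$ea[3] + es$ed, 100)
    expect_true(all(es$ea >= 0 & es$ea <= 100))
    # definition check against directly computed energies
    ae <- vapply(d$approx, function(v) sum(v^2), numeric(1))
    de <- vapply(d$detail, function(v) sum(v^2), numeric(1))
    for (j in 1:3) {
      expect_equal(es$ea[j], 100 * ae[j] / (ae[j] + sum(de[1:j])))
    }
    expect_equal(es$ea_std, sqrt(mean((es$ea - mean(es$ea))^2)))
  }
  zero <- dwt_multilevel(rep(1, 8))
  zero$approx <- lapply(zero$approx, function(v) v * 0)
  zero$detail <- lapply(zero$detail, function(v) v * 0)
  expect_error(dwt_energy_summary(zero), "all-zero")
})

test_that("wpt_energy_summary normalizes terminal-node energies", {
  w <- wpt_level3(rep(2, 8))
  es <- wpt_energy_summary(w)
  expect_equal(es$relative, c(100, rep(0, 7)))
  expect_equal(es$total, sum(rep(2, 8)^2))
  for (i in 1:20) {
    s <- with_seed2(5000 + i, rnorm(8))
    es <- wpt_energy_summary(wpt_level3(s))
    expect_lt(abs(sum(es$relative) - 100), 1e-9)
    expect_lt(abs(es$total - sum(s^2)), 1e-9)
  }
})

test_that("the five entropies match their formulas and conventions", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(2 * sqrt(2), rep(0, 7))), -8 * log(8))
  expect_equal(log_energy_entropy(c(1, 1)), 0)
  expect_equal(log_energy_entropy(2 * sqrt(2)), log(8))
  tsn <- threshold_sure_norm_entropies(c(0.1, 0.3, 0.25, 0.05))
  expect_equal(tsn$threshold, 2)
  expect_equal(threshold_sure_norm_entropies(c(1, 2))$sure, 5)
  expect_equal(threshold_sure_norm_entropies(c(1, -1))$norm, 2)

  # E[0] = 0 for all five, and invariance under zero-padding
  expect_equal(unname(entropy_vector(rep(0, 6))), rep(0, 5))
  for (i in 1:100) {
    s <- with_seed2(6000 + i, rnorm(sample(3:12, 1)) * 3)
    ev <- entropy_vector(s)
    expect_equal(ev, oracle_entropies(s), tolerance = 1e-12)
    expect_equal(entropy_vector(c(s, 0, 0, 0)), ev)
  }
})
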