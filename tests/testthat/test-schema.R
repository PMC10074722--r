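test_that("canonical column vocabulary has the documented block structure", {
  cols <- traditional_columns()
  expect_length(cols, 43L)
  expect_false(anyDuplicated(cols) > 0)
  expect_length(traditional_columns("asa_mono"), 8L)
  expect_length(traditional_columns("asa_comp"), 8L)
  expect_length(traditional_columns("asa_delta"), 8L)
  expect_length(traditional_columns("dssp"), 6L)
  expect_length(traditional_columns("dpx_cx"), 12L)
  expect_identical(traditional_columns("hbond"), "hbond_count")
  expect_length(full175_columns(), 175L)
  # the sidecar schema shipped with the package matches the constant
  sidecar <- jsonlite::read_json(
    system.file("extdata", "traditional_schema.json", package = "hotwave"),
    simplifyVector = TRUE)
  expect_identical(sidecar$column_order, cols)
})

test_that("label_from_ddg applies the 1.0 kcal/mol rule with >= boundary", {
  expect_identical(label_from_ddg(1.0), 1L)
  expect_identical(label_from_ddg(0.999), 0L)
  expect_identical(label_from_ddg(-2.5), 0L)
  expect_error(label_from_ddg(NaN), "finite")
  # monotone non-decreasing; exactly {ddg >= 1} maps to 1
  grid <- seq(-3, 3, by = 0.125)
  lab <- label_from_ddg(grid)
  expect_true(all(diff(lab) >= 0))
  expect_identical(lab, as.integer(grid >= 1.0))
})

test_that("CSV round trip is the identity on valid tables", {
  tb <- simulate_table(simulation_config(n_pos = 7, n_neg = 11, seed = 42))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tb, path)
  back <- read_feature_table(path, stage = "traditional")
  expect_identical(names(back$features), names(tb$features))
  expect_equal(as.matrix(back$features), as.matrix(tb$features),
               tolerance = 0) # full double precision
  expect_identical(back$labels, tb$labels)
  expect_equal(back$meta$ddg, tb$meta$ddg, tolerance = 0)

  # tab-delimited input is auto-detected
  lines <- readLines(path)
  writeLines(gsub(",", "\t", lines, fixed = TRUE), path)
  tsv <- read_feature_table(path, stage = "traditional")
  expect_equal(as.matrix(tsv$features), as.matrix(tb$features), tolerance = 0)
})

test_that("schema violations are reported by name and coordinate", {
  tb <- simulate_table(simulation_config(n_pos = 3, n_neg = 4, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")

  dropped <- tb$features
  dropped$dssp_tco <- NULL
  expect_error(feature_table(dropped, stage = "traditional"), "dssp_tco")

  write_feature_table(tb, path)
  lines <- readLines(path)
  fields <- strsplit(lines[3], ",")[[1]]
  fields[7] <- "oops" # second data row, a feature column
  lines[3] <- paste(fields, collapse = ",")
  writeLines(lines, path)
  expect_error(read_feature_table(path, stage = "traditional"),
               "row 2.*|oops")

  expect_error(read_feature_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("0-row and 1-row tables survive the round trip", {
  tb <- simulate_table(simulation_config(n_pos = 1, n_neg = 1, seed = 5))
  empty <- feature_table(tb$features[0, ], stage = "traditional")
  one <- feature_table(tb$features[1, , drop = FALSE], stage = "traditional")
  p0 <- withr::local_tempfile(fileext = ".csv")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(empty, p0)
  expect_length(readLines(p0), 1L) # header only
  write_feature_table(one, p1)
  expect_length(readLines(p1), 2L)
  expect_equal(nrow(read_feature_table(p0, "traditional")$features), 0L)
  expect_equal(unname(as.matrix(read_feature_table(p1, "traditional")$features)),
               unname(as.matrix(one$features)), tolerance = 0)
})

test_that("split_summary reproduces benchmark bookkeeping ratios", {
  mk <- function(n_pos, n_neg, seed) {
    simulate_table(simulation_config(n_pos = n_pos, n_neg = n_neg, seed = seed))
  }
  sp <- dataset_split(train = mk(101, 170, 1), test = mk(30, 38, 2))
  s <- split_summary(sp)
  expect_identical(s["train", "ratio_fmt"], "0.594")
  expect_identical(s["test", "ratio_fmt"], "0.789")
  expect_equal(s$ratio, s$n_pos / s$n_neg)

  bal <- dataset_split(train = mk(10, 10, 3), test = mk(10, 10, 4))
  expect_equal(split_summary(bal)$ratio, c(1, 1))

  unlabeled <- mk(5, 5, 6)
  unlabeled$labels <- NULL
  expect_error(dataset_split(unlabeled, mk(5, 5, 7)), "labels")
})

test_that("residue_record validates identity and the 43-feature contract", {
  tr <- sentinel_traditional()
  rec <- residue_record("1abc", "A", 42L, "R", ddg = 1.2, traditional = tr)
  expect_s3_class(rec, "residue_record")
  expect_identical(rec$label, 1L)
  expect_error(residue_record("1abcd", "A", 1, "R", 0, tr), "4-character")
  expect_error(residue_record("1abc", "A", 1, "R", Inf, tr), "finite")
  expect_error(residue_record("1abc", "A", 1, "R", 0, tr[-1]), "43")
  bad <- tr; bad["hbond_count"] <- -1
  expect_error(residue_record("1abc", "A", 1, "R", 0, bad), "hbond")
})
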