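toy_features <- function() {
  data.frame(feature_id = c("F1", "F2", "F3"),
             mz = c(500.1, 600.2, 700.3), rt = c(5, 10, 15),
             s1 = c(1000, 0, 5000), s2 = c(900, 100, 4500),
             b1 = c(0, 50, 600))
}

toy_samples <- function() {
  data.frame(sample_id = c("s1", "s2", "b1"),
             role = c("sample", "sample", "blank"),
             strain = c("A", "A", ""), replicate = c(1, 2, 1))
}

test_that("feature tables round-trip and malformed cells are named", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(toy_features(), f)
  back <- read_feature_table(f, toy_samples())
  expect_equal(back, toy_features())
  bad <- toy_features(); bad$s2[2] <- NA
  fb <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(bad, fb)
  expect_error(read_feature_table(fb), "column 's2', row 2")
  noid <- toy_features(); names(noid)[1] <- "id"
  fn <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(noid, fn)
  expect_error(read_feature_table(fn), "feature_id")
})

test_that("MGF blocks round-trip with RT in minutes", {
  spec <- list(list(feature_id = "F1", title = "F1", precursor_mz = 655.5,
                    rt = 1.0,
                    peaks = data.frame(mz = c(101.1, 220.2, 330.3, 440.4,
                                              550.5),
                                       intensity = c(10, 20, 30, 40, 50))))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spec, f)
  expect_true(any(grepl("RTINSECONDS=60.00", readLines(f), fixed = TRUE)))
  back <- read_mgf(f)
  expect_length(back, 1)
  expect_equal(nrow(back[[1]]$peaks), 5)
  expect_equal(back[[1]]$rt, 1.0)
  expect_equal(back[[1]]$peaks$mz, spec[[1]]$peaks$mz, tolerance = 1e-4)
  writeLines(c("BEGIN IONS", "PEPMASS=100", "101.0 5"), f)
  expect_error(read_mgf(f), "unterminated")
})

test_that("RT correction shifts, interpolates and excludes deviant IS", {
  feats <- data.frame(feature_id = c("F1", "F2", "IS1"),
                      mz = c(500, 600, 556.2771), rt = c(5, 10, 8.3))
  std <- data.frame(name = "IS1", expected_rt = 8.0, mz = 556.2771)
  out <- rt_correct(feats, std)
  expect_equal(out$rt, c(4.7, 9.7, 8.0))
  # deviation beyond 0.8 min: excluded with a warning
  feats$rt[3] <- 8.9
  expect_warning(expect_error(rt_correct(feats, std), "no usable"),
                 "excluded")
  # two anchors define a linear drift; a feature between them interpolates
  feats2 <- data.frame(feature_id = c("A", "IS1", "IS2"),
                       mz = c(450, 556.2771, 756.5), rt = c(5, 4, 6))
  std2 <- data.frame(name = c("IS1", "IS2"), expected_rt = c(4.2, 6.6),
                     mz = c(556.2771, 756.5))
  out2 <- rt_correct(feats2, std2)
  expect_equal(out2$rt[1], 5.4)   # 4.2 + (5-4)/(6-4) * (6.6-4.2)
})

test_that("blank filtering applies the 10-fold rule with kept boundary", {
  feats <- data.frame(feature_id = c("F1", "F2", "F3"),
                      mz = c(500, 600, 700), rt = c(1, 2, 3),
                      s1 = c(5000, 6000, 100), b1 = c(600, 600, 0))
  samp <- data.frame(sample_id = c("s1", "b1"),
                     role = c("sample", "blank"),
                     strain = c("A", ""), replicate = c(1, 1))
  out <- blank_filter(feats, samp, 10)
  expect_setequal(out$feature_id, c("F2", "F3"))   # ratio 10 kept, blank 0 kept
  # monotonicity: raising the factor never keeps a removed feature
  set.seed(1)
  rf <- data.frame(feature_id = sprintf("F%02d", 1:40), mz = 500, rt = 1,
                   s1 = runif(40, 0, 1e4), b1 = runif(40, 0, 1e3))
  kept_prev <- NULL
  for (fac in c(2, 5, 10, 20, 50)) {
    kept <- blank_filter(rf, samp, fac)$feature_id
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("coverage percentages use the MS2 denominator", {
  cov <- coverage_stats(6470, 2347, 162, 444)
  expect_equal(cov$pct_annotated, 6.90)
  expect_equal(cov$pct_network, 18.92)
  expect_equal(coverage_stats(10, 5, 0)$pct_annotated, 0)
  expect_error(coverage_stats(10, 0, 0), "positive")
})
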