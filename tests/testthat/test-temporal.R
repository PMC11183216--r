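mk_csd_t <- function(v, fs = 1000, ann = NULL) {
  structure(list(values = v, spacing_um = 150, fs_hz = fs,
                 smoothing = "none", normalized = "raw",
                 channels = seq_len(nrow(v)), annotations = ann),
            class = "csd_matrix")
}

test_that("seizure-time normalization always yields 100 columns", {
  set.seed(20)
  for (dur in c(0.7, 1.33, 6)) {
    v <- matrix(rnorm(3 * round(dur * 1000)), 3)
    b <- normalize_seizure_time(mk_csd_t(v), interval = c(0, dur))
    expect_equal(ncol(b$values), 100)
  }
})

test_that("constant |CSD| fills every bin with the constant", {
  v <- matrix(-2, 4, 5000)
  b <- normalize_seizure_time(mk_csd_t(v), interval = c(0, 5))
  expect_true(all(abs(b$values - 2) < 1e-12))
})

test_that("a linear ramp produces the analytic bin means", {
  n <- 10000
  v <- matrix(seq(0, 1, length.out = n), 1)
  b <- normalize_seizure_time(mk_csd_t(v), interval = c(0, 10))
  expect_true(all(diff(b$values[1, ]) > 0))
  expect_equal(as.numeric(b$values[1, ]),
               (seq_len(100) - 0.5) / 100, tolerance = 1e-2)
})

test_that("too-short intervals raise a resolution error", {
  v <- matrix(1, 2, 50)
  expect_error(normalize_seizure_time(mk_csd_t(v), interval = c(0, 0.05)),
               class = "ictalcsd_resolution_error")
})

test_that("time-warp invariance: stretching the seizure leaves bins unchanged", {
  set.seed(21)
  coarse <- matrix(rep(rnorm(500), each = 2), 2, 500, byrow = TRUE)
  v1 <- coarse
  v2 <- coarse[, rep(seq_len(500), each = 3)]   # x3 uniform stretch
  b1 <- normalize_seizure_time(mk_csd_t(v1), interval = c(0, 0.5))
  b2 <- normalize_seizure_time(mk_csd_t(v2), interval = c(0, 1.5))
  expect_equal(b1$values, b2$values, tolerance = 0.02)
})

test_that("engagement matrix thresholds excess and normalizes per bin", {
  binned <- structure(list(values = matrix(1, 4, 100), bin_dur_s = 0.5,
                           channels = 1:4), class = "binned_csd")
  base <- tibble::tibble(contact = 1:4, mean = 1, sd = 0.1)
  em <- engagement_matrix(binned, base)
  expect_true(all(em$values == 0))       # at baseline mean: no outliers
  binned$values[2, 50] <- 10
  em2 <- engagement_matrix(binned, base)
  expect_equal(em2$values[2, 50], 1)     # point mass on the one outlier
  expect_equal(sum(em2$values[, 50]), 1)
  expect_true(all(colSums(em2$values) %in% c(0, 1)))
  expect_error(engagement_matrix(binned, NULL),
               class = "ictalcsd_baseline_error")
})

test_that("binary mode counts outliers instead of summing excess", {
  binned <- structure(list(values = matrix(0, 2, 100), bin_dur_s = 0.5,
                           channels = 1:2), class = "binned_csd")
  binned$values[1, 10] <- 100
  binned$values[2, 10] <- 3
  base <- tibble::tibble(contact = 1:2, mean = 1, sd = 0.5)
  soft <- engagement_matrix(binned, base)
  hard <- engagement_matrix(binned, base, binary = TRUE)
  expect_gt(soft$values[1, 10], 0.9)
  expect_equal(hard$values[, 10], c(0.5, 0.5))
})

test_that("engagement onset detects a noiseless step exactly", {
  expect_true(is.na(engagement_onset(rep(1, 100))$onset))
  s <- c(rep(0, 29), rep(1, 71))
  expect_equal(engagement_onset(s)$onset, 30)
  # shift-equivariance of the estimator on exact steps
  for (k in c(10, 45, 80)) {
    sk <- c(rep(0, k - 1), rep(1, 101 - k))
    expect_equal(engagement_onset(sk)$onset, k)
  }
  # decreasing series: no onset (late mean must exceed early mean)
  expect_true(is.na(engagement_onset(rev(s))$onset))
})

test_that("baseline binning guards fire", {
  v <- matrix(1, 2, 5000)
  ann <- tibble::tibble(name = "preictal", start_s = 0, end_s = 5)
  expect_error(engagement_baseline(mk_csd_t(v, ann = ann), 0.5),
               class = "ictalcsd_baseline_error")   # < 10 s of baseline
})

test_that("onset-zone default shows no supragranular engagement onset", {
  run <- quick_onset_run()
  binned <- normalize_seizure_time(run$csd)
  base <- engagement_baseline(run$csd, binned$bin_dur_s)
  em <- engagement_matrix(binned, base, partition = layer_partition())
  expect_true(is.na(engagement_onset(em$values["supragranular", ])$onset))
  # deep groups are engaged from the start: no spurious late onset either
  expect_gt(mean(em$values["infragranular", ] +
                   em$values["granular", ]), 0.8)
})
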