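mk_csd <- function(v, fs = 1000, ann = NULL, channels = seq_len(nrow(v))) {
  structure(list(values = v, spacing_um = 150, fs_hz = fs,
                 smoothing = "none", normalized = "raw", channels = channels,
                 annotations = ann), class = "csd_matrix")
}

test_that("layer partition is contiguous, exhaustive and ordered", {
  p <- layer_partition()
  expect_equal(nrow(p), 24)
  expect_equal(as.character(p$group[c(1, 10, 11, 13, 14, 24)]),
               c("supragranular", "supragranular", "granular", "granular",
                 "infragranular", "infragranular"))
  expect_true(!is.unsorted(p$group))
  expect_error(layer_partition(granular_start = 1))
})

test_that("peak-layer counts conserve events and respect the peak location", {
  v <- matrix(0.1, 24, 3000)
  ev <- c(0.5, 1.2, 2.1)
  for (tt in ev) v[2, round(tt * 1000)] <- 5   # max at contact 2
  pc <- peak_layer_counts(mk_csd(v), ev)
  expect_equal(pc$n, c(3L, 0L, 0L))
  expect_equal(sum(pc$n), length(ev))
  expect_equal(sum(peak_layer_counts(mk_csd(v), numeric(0))$n), 0)
})

test_that("ties in |CSD| go to the deepest contact", {
  v <- matrix(0, 24, 1000)
  v[c(5, 20), 500] <- 3   # exact tie, contacts 5 and 20
  pc <- peak_layer_counts(mk_csd(v), 0.499)
  expect_equal(pc$n, c(0L, 0L, 1L))
})

test_that("zone-by-layer chi-square matches the hand-computed Pearson sum", {
  hom <- zone_layer_chi2(c(50, 25, 25), c(50, 25, 25))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)
  o <- c(10, 10, 80); u <- c(80, 10, 10)
  got <- zone_layer_chi2(o, u)
  # direct sum((O-E)^2/E) oracle
  tab <- rbind(o, u)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E))
  expect_equal(got$df, 2)
  # invariant under swapping the zone rows
  expect_equal(zone_layer_chi2(u, o)$statistic, got$statistic)
  expect_warning(zone_layer_chi2(c(2, 2, 2), c(3, 3, 3)), "exact")
  expect_error(zone_layer_chi2(c(0, 0, 0), c(1, 1, 1)),
               class = "ictalcsd_degenerate_error")
})

test_that("deep versus superficial peak distributions separate at p < 1e-4", {
  # paired synthetic zones with >= 500 events each
  set.seed(44)
  deep <- c(rmultinom(1, 600, c(0.03, 0.25, 0.72)))
  sup <- c(rmultinom(1, 600, c(0.75, 0.15, 0.10)))
  expect_lt(zone_layer_chi2(deep, sup)$p_value, 1e-4)
})

test_that("sink/source stats isolate a single active group", {
  ann <- tibble::tibble(name = "seizure", start_s = 0, end_s = 1)
  v <- matrix(0, 24, 1000)
  v[11:13, ] <- 0.6           # granular sinks only
  v[14, 1] <- 1; v[1, 1] <- -1  # set scale anchors
  csd <- mk_csd(v, ann = ann)
  csd$normalized <- "sink01_sourceneg1"
  rep1 <- suppressWarnings(sink_source_layer_stats(list(csd), zone = "onset"))
  d <- rep1$per_recording
  gr <- d[d$group == "granular" & d$polarity == "sink", ]
  expect_equal(gr$mean, 0.6)
  sup <- d[d$group == "supragranular" & d$polarity == "sink", ]
  expect_equal(sup$n_values, 0L)
})

test_that("identical group distributions give a null t-test", {
  ann <- tibble::tibble(name = "seizure", start_s = 0, end_s = 1)
  # every contact carries the same sink/source distribution, so the
  # characteristic and remaining groups cannot differ
  base <- matrix(rep(c(0.4, -0.4), 500), 24, 1000, byrow = TRUE)
  csds <- lapply(1:4, function(i) {
    csd <- mk_csd(base, ann = ann)
    csd$normalized <- "sink01_sourceneg1"
    csd
  })
  rep0 <- sink_source_layer_stats(csds, zone = "onset")
  expect_true(all(is.na(rep0$tests$p_value) | rep0$tests$p_value > 0.9))
})

test_that("alternation index tracks constructed sign flips", {
  fs <- 1000
  v <- matrix(0, 6, 5000)
  ev <- c(1, 2, 3)
  for (tt in ev) {
    v[2, round(tt * fs) + 1] <- 2
    v[2, round((tt + 0.05) * fs) + 1] <- -1     # flips on contact 2
    v[3, round(tt * fs) + 1] <- 2
    v[3, round((tt + 0.05) * fs) + 1] <- 1.5    # persists on contact 3
  }
  ann <- tibble::tibble(name = "preictal", start_s = 0, end_s = 0.5)
  set.seed(10)
  v[, 1:500] <- rnorm(6 * 500, sd = 0.01)
  ai <- alternation_index(mk_csd(v, fs = fs, ann = ann), ev)
  expect_equal(ai$index[2], 1)
  expect_equal(ai$index[3], 0)
  expect_true(is.na(ai$index[5]))   # never above the noise floor
  expect_error(alternation_index(mk_csd(v, fs = fs, ann = ann), 4.999),
               class = "ictalcsd_degenerate_error")
})

test_that("sign-symmetric noise gives an alternation index near one half", {
  set.seed(11)
  fs <- 1000
  v <- matrix(rnorm(4 * 60000), 4)
  ann <- tibble::tibble(name = "preictal", start_s = 0, end_s = 10)
  ev <- seq(11, 58, by = 0.2)      # 236 events
  ai <- alternation_index(mk_csd(v, fs = fs, ann = ann), ev)
  ok <- ai$n_events >= 50
  expect_true(all(abs(ai$index[ok] - 0.5) < 0.12))
})

test_that("onset-zone simulation puts discharge peaks in the deep groups", {
  run <- quick_onset_run()
  pc <- peak_layer_counts(run$csd, run$det)
  expect_gt(sum(pc$n[2:3]) / sum(pc$n), 0.9)
  # alternation appears on motif-active contacts, not superficial ones
  ai <- alternation_index(run$csd, run$det)
  deep <- ai$index[ai$contact %in% 14:20]
  expect_gt(mean(deep, na.rm = TRUE), 0.7)
})
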