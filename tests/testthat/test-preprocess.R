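# Filter contracts are checked on probe sinusoids, measuring amplitude over
# the central half of the trace to avoid filtfilt edge transients.

mid_amp <- function(x) {
  n <- length(x)
  max(abs(x[(n %/% 4):(3 * n %/% 4)]))
}

probe_rec <- function(freq, fs = 2000, dur = 20, n_ch = 3, line = 50) {
  t <- (0:(dur * fs - 1)) / fs
  laminar_recording(matrix(rep(sin(2 * pi * freq * t), each = n_ch),
                           n_ch, length(t)),
                    fs_lfp_hz = fs, line_freq_hz = line)
}

test_that("LFP band preserves pass-band amplitude within 1%", {
  rec <- filter_bands(probe_rec(10), notch = FALSE)
  expect_true(abs(mid_amp(rec$lfp[1, ]) - 1) < 0.01)
})

test_that("DC offset is removed by the 0.2 Hz high-pass", {
  rec <- probe_rec(10)
  rec$lfp <- rec$lfp * 0 + 5
  out <- filter_bands(rec, notch = FALSE)
  expect_lt(mid_amp(out$lfp[1, ]), 0.05)
})

test_that("mains notch attenuates the line frequency below 5%", {
  out <- filter_bands(probe_rec(50))
  expect_lt(mid_amp(out$lfp[1, ]), 0.05)
  out60 <- filter_bands(probe_rec(60, line = 60))
  expect_lt(mid_amp(out60$lfp[1, ]), 0.05)
})

test_that("stop-band sinusoid is attenuated by at least 40 dB", {
  out <- filter_bands(probe_rec(900), notch = FALSE)
  expect_lt(20 * log10(mid_amp(out$lfp[1, ])), -40)
})

test_that("filtering is zero-phase", {
  set.seed(1)
  rec <- make_noise_rec(n_ch = 3, dur_s = 20, fs = 2000)
  out <- filter_bands(rec, notch = FALSE)
  cc <- ccf(rec$lfp[2, ], out$lfp[2, ], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges at or above Nyquist are rejected", {
  rec <- probe_rec(10, fs = 800)
  expect_error(filter_bands(rec, preprocess_params(lfp_band_hz = c(0.2, 500))),
               class = "ictalcsd_param_error")
})

test_that("interior bad channel is replaced by its neighbours' mean", {
  rec <- make_noise_rec(n_ch = 6, dur_s = 2, fs = 500)
  rec$lfp[3, ] <- 999
  out <- interpolate_bad_channels(rec, bad = 3, max_bad_fraction = 0.5)
  expect_equal(out$lfp[3, ], (rec$lfp[2, ] + rec$lfp[4, ]) / 2)
  expect_equal(out$channel_status[3], "interpolated")
  # idempotent: re-running with no bad channels changes nothing
  again <- interpolate_bad_channels(out)
  expect_identical(again$lfp, out$lfp)
})

test_that("two consecutive bad channels use 2/3-1/3 linear weights", {
  rec <- make_noise_rec(n_ch = 8, dur_s = 1, fs = 500)
  out <- interpolate_bad_channels(rec, bad = c(4, 5), max_bad_fraction = 0.5)
  expect_equal(out$lfp[4, ], (2 / 3) * rec$lfp[3, ] + (1 / 3) * rec$lfp[6, ])
  expect_equal(out$lfp[5, ], (1 / 3) * rec$lfp[3, ] + (2 / 3) * rec$lfp[6, ])
})

test_that("edge bad channel copies its nearest good neighbour", {
  rec <- make_noise_rec(n_ch = 6, dur_s = 1, fs = 500)
  out <- interpolate_bad_channels(rec, bad = 1, max_bad_fraction = 0.5)
  expect_equal(out$lfp[1, ], rec$lfp[2, ])
})

test_that("bad-channel guards trigger", {
  rec <- make_noise_rec(n_ch = 8, dur_s = 1, fs = 500)
  expect_error(interpolate_bad_channels(rec, bad = 1:8),
               class = "ictalcsd_unrecoverable_error")
  expect_error(interpolate_bad_channels(rec, bad = 1:4,
                                        max_bad_fraction = 0.25),
               class = "ictalcsd_unrecoverable_error")
})

test_that("constant profile has zero gradient; linear profile constant gradient", {
  n_ch <- 10; n <- 100
  const <- laminar_recording(matrix(3, n_ch, n), fs_lfp_hz = 100)
  g <- monopolar_to_gradient(const)
  expect_true(all(g$lfp == 0))
  slope_per_um <- 0.01
  prof <- slope_per_um * 150 * seq_len(n_ch)   # linear in depth, h = 150 um
  lin <- laminar_recording(matrix(prof, n_ch, n), fs_lfp_hz = 100)
  gl <- monopolar_to_gradient(lin)
  expect_true(all(abs(gl$lfp - slope_per_um * 150) < 1e-12))
})

test_that("monopolar -> gradient -> monopolar is identity up to a constant", {
  rec <- make_noise_rec(n_ch = 7, dur_s = 1, fs = 500)
  back <- gradient_to_monopolar(monopolar_to_gradient(rec))
  # cumulative-sum oracle: difference to original is the per-time reference
  diffs <- rec$lfp - back$lfp
  expect_lt(max(abs(sweep(diffs, 2, diffs[1, ]))), 1e-10)
  expect_error(gradient_to_monopolar(rec), class = "ictalcsd_state_error")
})

test_that("artifact flagging finds and pads an injected excursion", {
  rec <- make_noise_rec(n_ch = 4, dur_s = 20, fs = 500)
  rec$lfp[2, 5000:5050] <- 60
  iv <- flag_artifacts(rec, z_threshold = 10)
  expect_equal(nrow(iv), 1)
  expect_lt(iv$start_s, 5000 / 500)
  expect_gt(iv$end_s, 5050 / 500)
  clean <- make_noise_rec(n_ch = 4, dur_s = 10, fs = 500)
  expect_equal(nrow(flag_artifacts(clean, z_threshold = 10)), 0)
})
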