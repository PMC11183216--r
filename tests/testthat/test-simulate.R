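test_that("identical configs give byte-identical recordings and truth", {
  cfg <- quick_onset_config(seed = 3)
  a <- simulate_seizure(cfg)
  b <- simulate_seizure(cfg)
  expect_identical(a$recording$lfp, b$recording$lfp)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("recording duration and annotations follow the phase schedule", {
  cfg <- quick_onset_config(seed = 2)
  sim <- simulate_seizure(cfg)
  total <- cfg$preictal_s + 5.3 + 12
  expect_equal(ncol(sim$recording$lfp) / cfg$fs_lfp_hz, total)
  expect_equal(sim$truth$seizure_onset_s, cfg$preictal_s)
  expect_equal(sim$truth$seizure_end_s, total)
  ev <- sim$truth$events
  expect_true(all(diff(ev$onset_s) >= 0.08 - 1e-9))  # waveform dead time
  expect_true(all(ev$time_s > cfg$preictal_s & ev$time_s < total))
  expect_equal(ev$onset_s, sort(ev$onset_s))
})

test_that("zero-amplitude motifs give pure noise with Poisson times intact", {
  motifs <- default_motifs("onset")
  motifs <- lapply(motifs, function(m) { m$amplitude <- 0; m })
  cfg <- quick_onset_config(seed = 5, motifs = motifs)
  sim <- simulate_seizure(cfg)
  expect_gt(nrow(sim$truth$events), 10)
  # no discharge energy: ictal variance matches pre-ictal variance
  fs <- cfg$fs_lfp_hz
  pre <- sim$recording$lfp[, 1:(10 * fs)]
  ict <- sim$recording$lfp[, (10 * fs + 1):(22 * fs)]
  # 1/f noise has slowly wandering variance; band-limit the comparison
  hp <- signal::butter(2, 1 / (fs / 2), "high")
  vp <- var(signal::filtfilt(hp, pre[12, ]))
  vi <- var(signal::filtfilt(hp, ict[12, ]))
  expect_lt(abs(vi / vp - 1), 0.5)
})

test_that("ground-truth rates converge to the configured schedule", {
  # constant phase: mean rate within 2 SEM of 7.1 Hz over seeds,
  # and dead-time-shifted intervals are exponential (KS test, pooled)
  rates <- c()
  gaps <- c()
  for (s in 1:12) {
    sim <- simulate_seizure(quick_onset_config(seed = 100 + s))
    b <- sim$truth$phase_boundaries_s
    ev <- sim$truth$events$onset_s
    in2 <- ev[ev >= b[2] & ev < b[3]]
    rates <- c(rates, length(in2) / (b[3] - b[2]))
    gaps <- c(gaps, diff(in2))
  }
  sem <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 7.1), 2 * sem + 0.15)
  lambda_star <- 7.1 / (1 - 7.1 * 0.08)
  ks <- suppressWarnings(ks.test(gaps - 0.08, "pexp", lambda_star))
  expect_gt(ks$p.value, 0.01)
})

test_that("first-second rate matches the configured starting rate", {
  n1 <- vapply(1:15, function(s) {
    sim <- simulate_seizure(quick_onset_config(seed = 200 + s))
    sum(sim$truth$events$onset_s >= 10 & sim$truth$events$onset_s < 11)
  }, numeric(1))
  expect_lt(abs(mean(n1) - 1.3), 2 * sd(n1) / sqrt(length(n1)) + 0.3)
})

test_that("noiseless discharge CSD is proportional to the motif profile", {
  cfg <- simulation_config(
    zone = "onset", bands = "lfp",
    phases = list(phase_spec(12, 1, 1, "deep_flank")),
    noise = list(pink_sigma = 0, line_freq_hz = 50, line_amplitude = 0),
    seed = 9)
  sim <- simulate_seizure(cfg)
  ev <- sim$truth$events
  expect_gt(nrow(ev), 0)
  csd <- compute_csd(sim$recording, vaknin = TRUE, smooth = FALSE)
  pk <- round(ev$time_s[1] * 2000) + 1
  got <- csd$values[, pk]
  want <- default_motifs("onset")$deep_flank$csd_profile
  cosine <- sum(got * want) / sqrt(sum(got^2) * sum(want^2))
  expect_gt(cosine, 0.99)
  # current conservation: summed unsmoothed CSD over contacts ~ 0
  sums <- colSums(csd$values)
  expect_lt(max(abs(sums)) / max(abs(csd$values)), 1e-6)
})

test_that("onset default embeds two disjoint motifs, propagation one plus recruits", {
  on <- quick_onset_config(seed = 1)
  expect_setequal(
    unique(vapply(on$phases, `[[`, character(1), "motif_id")),
    c("deep_flank", "deep_broad"))
  pr <- quick_propagation_config(seed = 1)
  expect_equal(pr$phases[[1]]$motif_id, "superficial")
  expect_equal(pr$recruitment$fraction, c(0.28, 0.42))
  # every default motif is zero-sum
  for (m in c(on$motifs, pr$motifs))
    expect_lt(abs(sum(m$csd_profile)), 1e-10)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_contacts = 4), "n_contacts")
  expect_error(simulation_config(preictal_s = 5), "preictal")
  expect_error(simulation_config(fs_mua_hz = 3000), "fs_mua_hz")
  expect_error(
    simulation_config(phases = list(phase_spec(10, 1, 1, "no_such_motif"))),
    class = "ictalcsd_config_error")
  # rate infeasible with the dead time
  expect_error(
    simulation_config(phases = list(phase_spec(10, 13, 13, "deep_flank"))),
    "dead time")
})
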