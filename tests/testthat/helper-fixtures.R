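# Shared fixtures, built in code. Expensive simulations are cached for the
# session so several test files can reuse them.

.fx <- new.env(parent = emptyenv())

# White-noise monopolar recording with preictal/seizure annotations.
make_noise_rec <- function(n_ch = 8, dur_s = 30, fs = 500, seed = 7,
                           preictal_s = min(12, 0.4 * dur_s), sd = 1) {
  set.seed(seed)
  n <- dur_s * fs
  laminar_recording(
    lfp = matrix(rnorm(n_ch * n, sd = sd), n_ch, n),
    fs_lfp_hz = fs, spacing_um = 150,
    annotations = tibble::tibble(name = c("preictal", "seizure"),
                                 start_s = c(0, preictal_s),
                                 end_s = c(preictal_s, dur_s)))
}

# Short onset-zone seizure (LFP only) for fast unit tests: full phase-1
# dynamics, abbreviated constant phase.
quick_onset_config <- function(seed = 1, ...) {
  simulation_config(
    zone = "onset", bands = "lfp",
    phases = list(phase_spec(5.3, 1.3, 8.9, "deep_flank", ramp_delay_s = 1),
                  phase_spec(12, 7.1, 7.1, "deep_broad")),
    seed = seed, ...)
}

quick_propagation_config <- function(seed = 1, ...) {
  simulation_config(zone = "propagation", bands = "lfp",
                    phases = list(phase_spec(25, 7.1, 7.1, "superficial")),
                    seed = seed, ...)
}

cached <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# One short onset simulation + detection + CSD, shared across files.
quick_onset_run <- function() {
  cached("onset_run", {
    sim <- simulate_seizure(quick_onset_config(seed = 11))
    rec <- filter_bands(sim$recording)
    det <- detect_discharges(rec)
    csd <- compute_csd(rec)
    list(sim = sim, rec = rec, det = det, csd = csd)
  })
}

# A zero-sum laminar profile for forward-model tests.
random_zero_sum <- function(n, seed) {
  set.seed(seed)
  p <- rnorm(n)
  p - mean(p)
}
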