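#' Seizure phase specification
#'
#' One temporal phase of a simulated seizure: a discharge-rate profile and
#' the motif active during the phase. The rate is `rate_start_hz` for the
#' first `ramp_delay_s` seconds, then ramps linearly to `rate_end_hz` by the
#' end of the phase.
#'
#' @param duration_s phase duration (s), > 0.
#' @param rate_start_hz,rate_end_hz discharge rate at phase start/end (Hz).
#' @param motif_id motif active during the phase.
#' @param ramp_delay_s seconds the rate is held at `rate_start_hz` before the
#'   linear ramp begins (0 = ramp from phase onset).
#' @return object of class `phase_spec`.
#' @export
phase_spec <- function(duration_s, rate_start_hz, rate_end_hz = rate_start_hz,
                       motif_id, ramp_delay_s = 0) {
  if (duration_s <= 0) rlang::abort("duration_s must be > 0.")
  if (rate_start_hz < 0 || rate_end_hz < 0) rlang::abort("rates must be >= 0.")
  if (ramp_delay_s < 0 || ramp_delay_s > duration_s)
    rlang::abort("ramp_delay_s must lie within the phase.")
  structure(list(duration_s = duration_s, rate_start_hz = rate_start_hz,
                 rate_end_hz = rate_end_hz, motif_id = motif_id,
                 ramp_delay_s = ramp_delay_s),
            class = "phase_spec")
}

# rate at time t (s, relative to phase start)
phase_rate_at <- function(phase, t) {
  if (t <= phase$ramp_delay_s) return(phase$rate_start_hz)
  span <- phase$duration_s - phase$ramp_delay_s
  if (span <= 0) return(phase$rate_end_hz)
  f <- (t - phase$ramp_delay_s) / span
  phase$rate_start_hz + f * (phase$rate_end_hz - phase$rate_start_hz)
}

#' Simulation configuration
#'
#' Study-condition defaults follow the dynamics of human focal seizures
#' recorded on 24-contact laminar arrays: onset-zone seizures start with a
#' ~5.3 s initiation phase whose discharge rate holds at 1.3 Hz over the
#' first second and ramps to 8.9 Hz, followed by a 57 s phase at a constant
#' 7.1 Hz with a different deep laminar motif. Propagation-zone seizures run
#' a single supragranular motif at 7.1 Hz with granular and infragranular
#' components recruited at 28% and 42% of normalized seizure time.
#'
#' @param zone `"onset"` or `"propagation"`.
#' @param n_contacts number of contacts (>= 5; default 24).
#' @param spacing_um contact spacing (default 150).
#' @param fs_lfp_hz,fs_mua_hz sampling rates (defaults 2000 / 20000;
#'   `fs_mua_hz > 2 * fs_lfp_hz` required).
#' @param preictal_s pre-ictal baseline duration (>= 10 s).
#' @param phases ordered list of [phase_spec()]; `NULL` = zone default.
#' @param motifs named list of [laminar_motif()]; `NULL` = [default_motifs()].
#' @param recruitment tibble `(motif_id, fraction)`: motifs switched on once
#'   normalized seizure time reaches `fraction` (propagation default:
#'   granular 0.28, infragranular 0.42).
#' @param noise list: `pink_sigma` (uV, per-channel 1/f noise SD),
#'   `line_freq_hz` (50 or 60), `line_amplitude` (uV).
#' @param target_z discharge peak amplitude on the potential-gradient
#'   channels in units of the gradient noise SD (default 10).
#' @param alternation_prob probability that a discharge's second lobe flips
#'   spatial polarity (default 1).
#' @param bands character subset of `c("lfp", "mua")` to synthesize.
#' @param mua list of MUA-band parameters: `base_rate_hz` spontaneous rate,
#'   `locked_rate_hz` peak discharge-locked rate scale, `locked_window_s`
#'   discharge-locked firing window, `noise_sigma` (uV), `spike_snr` spike
#'   amplitude over noise SD.
#' @param seed integer RNG seed; identical configs give identical recordings.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(zone = "onset", n_contacts = 24,
                              spacing_um = 150, fs_lfp_hz = 2000,
                              fs_mua_hz = 20000, preictal_s = 10,
                              phases = NULL, motifs = NULL,
                              recruitment = NULL,
                              noise = list(pink_sigma = 15, line_freq_hz = 50,
                                           line_amplitude = 10),
                              target_z = 10, alternation_prob = 1,
                              bands = c("lfp", "mua"),
                              mua = list(base_rate_hz = 1, locked_rate_hz = 80,
                                         locked_window_s = 0.03,
                                         noise_sigma = 5, spike_snr = 8),
                              seed = 1L) {
  zone <- match.arg(zone, c("onset", "propagation"))
  if (n_contacts < 5)
    rlang::abort("n_contacts must be >= 5 (CSD needs interior channels).")
  if (preictal_s < 10)
    rlang::abort("preictal_s must be >= 10 (baseline rule).")
  if (fs_mua_hz <= 2 * fs_lfp_hz)
    rlang::abort("fs_mua_hz must exceed 2 * fs_lfp_hz.")
  if (!noise$line_freq_hz %in% c(50, 60))
    rlang::abort("line_freq_hz must be 50 or 60.")
  if (is.null(motifs)) motifs <- default_motifs(zone, n_contacts)
  if (is.null(phases)) {
    phases <- if (zone == "onset") {
      list(phase_spec(5.3, 1.3, 8.9, "deep_flank", ramp_delay_s = 1),
           phase_spec(57, 7.1, 7.1, "deep_broad"))
    } else {
      list(phase_spec(62.3, 7.1, 7.1, "superficial"))
    }
  }
  if (is.null(recruitment)) {
    recruitment <- if (zone == "propagation") {
      tibble::tibble(motif_id = c("recruit_granular", "recruit_infra"),
                     fraction = c(0.28, 0.42))
    } else {
      tibble::tibble(motif_id = character(), fraction = numeric())
    }
  }
  recruitment <- tibble::as_tibble(recruitment)
  if (nrow(recruitment) &&
      any(recruitment$fraction < 0 | recruitment$fraction > 1))
    rlang::abort("recruitment fractions must lie in [0, 1].")
  for (ph in phases) {
    if (!ph$motif_id %in% names(motifs))
      rlang::abort(sprintf("phase motif '%s' missing from the motif table.",
                           ph$motif_id),
                   class = "ictalcsd_config_error")
    tau <- motifs[[ph$motif_id]]$duration_ms / 1000
    if (max(ph$rate_start_hz, ph$rate_end_hz) * tau >= 0.95)
      rlang::abort(sprintf(
        "rate %.1f Hz infeasible with a %.0f ms discharge waveform (dead time).",
        max(ph$rate_start_hz, ph$rate_end_hz), tau * 1000))
  }
  if (nrow(recruitment) && !all(recruitment$motif_id %in% names(motifs)))
    rlang::abort("recruitment references motifs missing from the motif table.",
                 class = "ictalcsd_config_error")
  structure(list(zone = zone, n_contacts = n_contacts, spacing_um = spacing_um,
                 fs_lfp_hz = fs_lfp_hz, fs_mua_hz = fs_mua_hz,
                 preictal_s = preictal_s, phases = phases, motifs = motifs,
                 recruitment = recruitment, noise = noise,
                 target_z = target_z, alternation_prob = alternation_prob,
                 bands = bands, mua = mua, seed = as.integer(seed)),
            class = "simulation_config")
}

# Draw discharge onset times for one phase via a dead-time-corrected renewal
# process: intervals are tau + Exp(lambda*) with lambda* = r/(1 - r*tau), so
# the realised mean rate equals the configured rate r exactly. The first
# event is drawn from the equilibrium forward-recurrence distribution so the
# rate is correct from the first second onward.
draw_phase_events <- function(phase, tau, t0) {
  times <- numeric(0)
  r0 <- phase_rate_at(phase, 0)
  if (r0 <= 0 && phase$rate_end_hz <= 0) return(times)
  mu0 <- tau + (1 - r0 * tau) / r0
  # equilibrium forward recurrence time for interval X = tau + Exp(lambda*)
  first <- if (stats::runif(1) < tau / mu0) {
    stats::runif(1, 0, tau)
  } else {
    tau + stats::rexp(1, r0 / (1 - r0 * tau))
  }
  t <- first
  while (t < phase$duration_s) {
    times <- c(times, t0 + t)
    r <- phase_rate_at(phase, min(t + tau, phase$duration_s))
    if (r <= 0) break
    t <- t + tau + stats::rexp(1, r / (1 - r * tau))
  }
  times
}

#' Simulate a laminar seizure recording with ground truth
#'
#' Generates a pre-ictal baseline followed by the configured seizure phases.
#' Each discharge injects `waveform x forward_lfp_from_csd(active motif)`
#' into the LFP, with the spatial polarity of the kernel's second lobe
#' inverted `alternation_lag_ms` after onset. Per-channel 1/f noise and a
#' mains-frequency sinusoid are added. The MUA band holds 1-ms biphasic
#' spike templates from inhomogeneous Poisson trains (spontaneous rate plus
#' discharge-locked firing shaped by each motif's depth profile) in white
#' noise. Identical configs (including the seed) give identical output.
#'
#' @param config a [simulation_config()].
#' @return list with class `laminar_sim`: `recording` (a
#'   [laminar_recording()]) and `truth`, a list holding `events` (tibble:
#'   `time_s` = discharge peak time, `onset_s`, `motif_id`, `phase`,
#'   `alternated`), `phase_boundaries_s`, `recruitment`, `seizure_onset_s`,
#'   `seizure_end_s`, `mua_spike_times` (per contact) and the calibrated
#'   motif scales.
#' @export
simulate_seizure <- function(config) {
  if (!inherits(config, "simulation_config"))
    rlang::abort("`config` must come from simulation_config().")
  set.seed(config$seed)
  fs <- config$fs_lfp_hz
  nch <- config$n_contacts
  seiz_dur <- sum(vapply(config$phases, `[[`, numeric(1), "duration_s"))
  total_s <- config$preictal_s + seiz_dur
  n_lfp <- round(total_s * fs)
  t_axis <- (seq_len(n_lfp) - 1) / fs

  ## --- noise bed -----------------------------------------------------------
  lfp <- matrix(0, nch, n_lfp)
  for (i in seq_len(nch))
    lfp[i, ] <- pink_noise(n_lfp) * config$noise$pink_sigma
  line_phase <- stats::runif(1, 0, 2 * pi)
  line_gain <- stats::runif(nch, 0.9, 1.1)
  line_wave <- sin(2 * pi * config$noise$line_freq_hz * t_axis + line_phase)
  lfp <- lfp + config$noise$line_amplitude * (line_gain %o% rep(1, n_lfp)) *
    rep(line_wave, each = nch)

  ## --- amplitude calibration ----------------------------------------------
  # Scale each motif so its peak response on the potential-gradient channels
  # is target_z times the realised gradient noise SD (times the motif's
  # relative amplitude).
  pre_idx <- seq_len(round(config$preictal_s * fs))
  grad_noise <- diff(lfp[, pre_idx])        # (nch-1) x n gradient of noise
  # Calibrate against the in-band (0.2-500 Hz) noise floor: this is the
  # floor a detector sees after standard band-limiting, and 1/f noise keeps
  # most of its power below the band.
  hp <- signal::butter(2, 0.2 / (fs / 2), type = "high")
  lp <- signal::butter(4, min(500, 0.45 * fs) / (fs / 2), type = "low")
  sigma_grad <- apply(grad_noise, 1, function(row)
    robust_sd(signal::filtfilt(lp, signal::filtfilt(hp, row))))
  # noise-free configurations: fall back to a unit floor so motifs are
  # injected at a well-defined (arbitrary) scale
  sigma_grad <- pmax(sigma_grad, .Machine$double.eps)
  motif_fields <- lapply(config$motifs, function(m) {
    phi <- forward_lfp_from_csd(m$csd_profile, config$spacing_um)
    zmax <- max(abs(diff(phi)) / sigma_grad)  # largest per-channel z response
    scale <- if (zmax > 0) config$target_z * m$amplitude / zmax else 0
    list(phi = phi * scale, scale = scale)
  })

  ## --- discharge times -----------------------------------------------------
  onset_s <- config$preictal_s
  boundaries <- onset_s + cumsum(c(0, vapply(config$phases, `[[`, numeric(1),
                                             "duration_s")))
  ev_onset <- numeric(0); ev_phase <- integer(0)
  for (k in seq_along(config$phases)) {
    ph <- config$phases[[k]]
    tau <- config$motifs[[ph$motif_id]]$duration_ms / 1000
    tk <- draw_phase_events(ph, tau, boundaries[k])
    ev_onset <- c(ev_onset, tk)
    ev_phase <- c(ev_phase, rep(k, length(tk)))
  }
  # enforce the minimum gap across phase boundaries too
  if (length(ev_onset) > 1) {
    keep <- c(TRUE, diff(ev_onset) >=
                vapply(ev_phase[-1], function(k) {
                  config$motifs[[config$phases[[k]]$motif_id]]$duration_ms / 1000
                }, numeric(1)) - 1e-9)
    ev_onset <- ev_onset[keep]; ev_phase <- ev_phase[keep]
  }
  ev_motif <- vapply(ev_phase, function(k) config$phases[[k]]$motif_id,
                     character(1))
  alternated <- stats::runif(length(ev_onset)) < config$alternation_prob

  ## --- inject discharges ---------------------------------------------------
  norm_time <- (ev_onset - onset_s) / seiz_dur
  peak_times <- numeric(length(ev_onset))
  for (e in seq_along(ev_onset)) {
    m <- config$motifs[[ev_motif[e]]]
    phi <- motif_fields[[ev_motif[e]]]$phi
    # recruited components switch on at their fraction of normalized time
    if (nrow(config$recruitment)) {
      on <- config$recruitment$fraction <= norm_time[e]
      for (rm in config$recruitment$motif_id[on])
        phi <- phi + motif_fields[[rm]]$phi
    }
    lag_s <- m$alternation_lag_ms / 1000
    dur_s <- m$duration_ms / 1000
    n1 <- round(lag_s * fs); n2 <- round((dur_s - lag_s) * fs)
    w1 <- 0.5 * (1 - cos(2 * pi * seq_len(n1) / n1))
    w2 <- 0.5 * (1 - cos(2 * pi * seq_len(n2) / n2))
    flip <- if (alternated[e]) -1 else 1
    kern <- c(w1, flip * m$second_lobe_gain * w2)
    i0 <- round(ev_onset[e] * fs) + 1L
    idx <- i0:(i0 + length(kern) - 1L)
    ok <- idx <= n_lfp
    lfp[, idx[ok]] <- lfp[, idx[ok]] + phi %o% kern[ok]
    peak_times[e] <- (i0 - 1L + round(n1 / 2)) / fs  # first-lobe peak
  }

  ## --- MUA band ------------------------------------------------------------
  mua <- NULL; mua_spikes <- NULL
  if ("mua" %in% config$bands) {
    fsm <- config$fs_mua_hz
    n_mua <- round(total_s * fsm)
    mua <- matrix(stats::rnorm(nch * n_mua, sd = config$mua$noise_sigma),
                  nch, n_mua)
    # 1-ms biphasic spike template
    nt <- round(fsm / 1000)
    tt <- seq_len(nt) / nt
    template <- sin(2 * pi * tt) * 0.5 * (1 - cos(2 * pi * tt))
    template <- template / max(abs(template)) *
      config$mua$spike_snr * config$mua$noise_sigma
    mua_spikes <- vector("list", nch)
    for (i in seq_len(nch)) {
      # spontaneous firing over the whole recording
      n_sp <- stats::rpois(1, config$mua$base_rate_hz * total_s)
      sp <- stats::runif(n_sp, 0, total_s)
      # discharge-locked firing
      for (e in seq_along(ev_onset)) {
        w <- config$motifs[[ev_motif[e]]]$mua_depth_profile[i]
        if (w <= 0) next
        lam <- w * config$mua$locked_rate_hz * config$mua$locked_window_s
        k <- stats::rpois(1, lam)
        if (k > 0)
          sp <- c(sp, ev_onset[e] + stats::runif(k, 0, config$mua$locked_window_s))
      }
      sp <- sort(sp[sp < total_s - 2 / 1000])
      if (length(sp) > 1)  # 1 ms refractory
        sp <- sp[c(TRUE, diff(sp) >= 1e-3)]
      mua_spikes[[i]] <- sp
      if (length(sp)) {
        amp <- exp(stats::rnorm(length(sp), 0, 0.1))
        for (s in seq_along(sp)) {
          j0 <- round(sp[s] * fsm) + 1L
          jj <- j0:(j0 + nt - 1L)
          mua[i, jj] <- mua[i, jj] + amp[s] * template
        }
      }
    }
  }

  ann <- tibble::tibble(
    name = c("preictal", "seizure"),
    start_s = c(0, onset_s),
    end_s = c(onset_s, total_s))
  rec <- laminar_recording(
    lfp = lfp, fs_lfp_hz = fs,
    mua = mua, fs_mua_hz = if (is.null(mua)) NULL else config$fs_mua_hz,
    spacing_um = config$spacing_um, signal_kind = "monopolar",
    zone = config$zone, line_freq_hz = config$noise$line_freq_hz,
    annotations = ann)
  truth <- list(
    events = tibble::tibble(time_s = peak_times, onset_s = ev_onset,
                            motif_id = ev_motif, phase = ev_phase,
                            alternated = alternated),
    phase_boundaries_s = boundaries,
    recruitment = config$recruitment,
    seizure_onset_s = onset_s, seizure_end_s = total_s,
    mua_spike_times = mua_spikes,
    motif_scales = vapply(motif_fields, `[[`, numeric(1), "scale"),
    sigma_grad = sigma_grad)
  structure(list(recording = rec, truth = truth, config = config),
            class = "laminar_sim")
}

#' @export
print.laminar_sim <- function(x, ...) {
  cat(sprintf("<laminar_sim> zone %s, %d ground-truth discharges, seed %d\n",
              x$config$zone, nrow(x$truth$events), x$config$seed))
  print(x$recording)
  invisible(x)
}
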