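#' Preprocessing parameters
#'
#' @param lfp_band_hz length-2 numeric, LFP band edges in Hz
#'   (default `c(0.2, 500)`).
#' @param mua_highpass_hz MUA high-pass edge (default 300). Set
#'   `mua_band_hz` to use a band-pass instead.
#' @param mua_band_hz optional length-2 numeric; when given, the MUA band is
#'   band-passed (e.g. `c(200, 5000)`) instead of high-passed.
#' @param notch_bandwidth_hz width of the mains notch (default 2).
#' @param artifact_z_threshold robust z beyond which samples are flagged as
#'   artifact (default 10).
#' @param max_bad_fraction largest tolerated fraction of bad channels before
#'   interpolation refuses (default 0.25).
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(lfp_band_hz = c(0.2, 500), mua_highpass_hz = 300,
                              mua_band_hz = NULL, notch_bandwidth_hz = 2,
                              artifact_z_threshold = 10,
                              max_bad_fraction = 0.25) {
  if (lfp_band_hz[1] <= 0 || lfp_band_hz[1] >= lfp_band_hz[2])
    rlang::abort("need 0 < low < high for lfp_band_hz.")
  if (notch_bandwidth_hz <= 0) rlang::abort("notch_bandwidth_hz must be > 0.")
  structure(list(lfp_band_hz = lfp_band_hz, mua_highpass_hz = mua_highpass_hz,
                 mua_band_hz = mua_band_hz,
                 notch_bandwidth_hz = notch_bandwidth_hz,
                 artifact_z_threshold = artifact_z_threshold,
                 max_bad_fraction = max_bad_fraction),
            class = "preprocess_params")
}

# Zero-phase Butterworth filtering of the rows of a matrix.
filt_rows <- function(x, filt) {
  t(apply(x, 1, function(row) signal::filtfilt(filt, row)))
}

#' Band-limit the LFP and MUA bands (zero phase)
#'
#' LFP: 4th-order Butterworth low-pass at the upper band edge plus a
#' 2nd-order high-pass at the lower edge (the 0.2 Hz edge sits at 1e-4 of
#' Nyquist, where higher orders are numerically fragile), followed by a
#' 2nd-order band-stop of `notch_bandwidth_hz` around the recording's mains
#' frequency. MUA: 4th-order high-pass (or band-pass). All filters are
#' applied forward-backward, so the net filter has zero phase.
#'
#' @param rec a [laminar_recording()].
#' @param params a [preprocess_params()].
#' @param notch apply the mains notch (default TRUE).
#' @return the recording with filtered bands.
#' @export
filter_bands <- function(rec, params = preprocess_params(), notch = TRUE) {
  nyq <- rec$fs_lfp_hz / 2
  if (params$lfp_band_hz[2] >= nyq)
    rlang::abort("LFP band edge at or above Nyquist.",
                 class = "ictalcsd_param_error")
  lp <- signal::butter(4, params$lfp_band_hz[2] / nyq, type = "low")
  hp <- signal::butter(2, params$lfp_band_hz[1] / nyq, type = "high")
  x <- filt_rows(rec$lfp, lp)
  x <- filt_rows(x, hp)
  if (notch) {
    bw <- params$notch_bandwidth_hz / 2
    bs <- signal::butter(2, c(rec$line_freq_hz - bw, rec$line_freq_hz + bw) / nyq,
                         type = "stop")
    x <- filt_rows(x, bs)
  }
  rec$lfp <- x
  if (!is.null(rec$mua)) {
    nyqm <- rec$fs_mua_hz / 2
    if (!is.null(params$mua_band_hz)) {
      if (params$mua_band_hz[2] >= nyqm)
        rlang::abort("MUA band edge at or above Nyquist.",
                     class = "ictalcsd_param_error")
      bp <- signal::butter(4, params$mua_band_hz / nyqm, type = "pass")
      rec$mua <- filt_rows(rec$mua, bp)
    } else {
      if (params$mua_highpass_hz >= nyqm)
        rlang::abort("MUA high-pass edge at or above Nyquist.",
                     class = "ictalcsd_param_error")
      hpm <- signal::butter(4, params$mua_highpass_hz / nyqm, type = "high")
      rec$mua <- filt_rows(rec$mua, hpm)
    }
  }
  rec
}

#' Interpolate bad channels linearly in depth
#'
#' Interior bad channels are replaced by the distance-weighted linear
#' interpolation between the nearest good channels above and below; bad
#' channels at the array edge are copied from the nearest good channel.
#'
#' @param rec a [laminar_recording()] (monopolar).
#' @param bad integer vector of bad channel indices (defaults to channels
#'   already marked `"bad"` in `channel_status`).
#' @param max_bad_fraction refuse when more than this fraction is bad.
#' @return recording with bad channels replaced and `channel_status` updated
#'   to `"interpolated"`.
#' @export
interpolate_bad_channels <- function(rec, bad = NULL, max_bad_fraction = 0.25) {
  n <- rec$n_contacts
  if (is.null(bad)) bad <- which(rec$channel_status == "bad")
  bad <- sort(unique(as.integer(bad)))
  if (!length(bad)) return(rec)
  if (length(bad) >= n)
    rlang::abort("all channels bad: recording unrecoverable.",
                 class = "ictalcsd_unrecoverable_error")
  if (length(bad) / n > max_bad_fraction)
    rlang::abort(sprintf("%.0f%% of channels bad exceeds the %.0f%% guard.",
                         100 * length(bad) / n, 100 * max_bad_fraction),
                 class = "ictalcsd_unrecoverable_error")
  good <- setdiff(seq_len(n), bad)
  for (b in bad) {
    above <- good[good < b]
    below <- good[good > b]
    if (length(above) && length(below)) {
      a <- max(above); d <- min(below)
      wa <- (d - b) / (d - a); wd <- (b - a) / (d - a)
      rec$lfp[b, ] <- wa * rec$lfp[a, ] + wd * rec$lfp[d, ]
    } else if (length(below)) {
      rec$lfp[b, ] <- rec$lfp[min(below), ]
    } else {
      rec$lfp[b, ] <- rec$lfp[max(above), ]
    }
  }
  rec$channel_status[bad] <- "interpolated"
  rec
}

#' Convert between monopolar and potential-gradient signals
#'
#' The gradient is the forward difference in depth,
#' `g[i] = phi[i+1] - phi[i]` (successive-contact differential recording).
#' Reconstruction integrates by cumulative sum with a zero reference at the
#' virtual contact above the array, so monopolar -> gradient -> monopolar is
#' the identity up to the reference constant per time point.
#'
#' @param rec a [laminar_recording()].
#' @return the converted recording (with `signal_kind` updated).
#' @export
monopolar_to_gradient <- function(rec) {
  if (rec$signal_kind != "monopolar")
    rlang::abort("recording is not monopolar.", class = "ictalcsd_state_error")
  rec$lfp <- diff(rec$lfp)   # (n-1) x t forward differences in depth
  rec$signal_kind <- "gradient"
  rec
}

#' @rdname monopolar_to_gradient
#' @export
gradient_to_monopolar <- function(rec) {
  if (rec$signal_kind != "gradient")
    rlang::abort("recording is not gradient.", class = "ictalcsd_state_error")
  g <- rec$lfp
  phi <- rbind(0, apply(g, 2, cumsum))
  rec$lfp <- phi
  rec$signal_kind <- "monopolar"
  rec
}

#' Flag high-amplitude artifact intervals automatically
#'
#' Replaces interactive artifact review with a reproducible rule: samples
#' whose robust z (per channel, median/MAD over the whole trace) exceeds the
#' threshold on any channel are flagged, and flagged runs are dilated by
#' `pad_ms` on both sides and merged.
#'
#' @param rec a [laminar_recording()].
#' @param z_threshold robust z threshold (default 10).
#' @param pad_ms padding around flagged samples (default 100).
#' @return tibble of artifact intervals (`start_s`, `end_s`).
#' @export
flag_artifacts <- function(rec, z_threshold = 10, pad_ms = 100) {
  z <- abs(sweep(sweep(rec$lfp, 1, apply(rec$lfp, 1, stats::median)), 1,
                 apply(rec$lfp, 1, robust_sd), "/"))
  hit <- apply(z > z_threshold, 2, any)
  if (!any(hit))
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values]) / rec$fs_lfp_hz
  pad <- pad_ms / 1000
  iv[, 1] <- pmax(iv[, 1] - pad, 0)
  iv[, 2] <- pmin(iv[, 2] + pad, ncol(rec$lfp) / rec$fs_lfp_hz)
  # merge overlapping padded intervals
  o <- order(iv[, 1]); iv <- iv[o, , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= merged[nrow(merged), 2]) {
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
    } else merged <- rbind(merged, iv[k, ])
  }
  tibble::tibble(start_s = merged[, 1], end_s = merged[, 2])
}
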