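#' Discharge detector parameters
#'
#' Amplitude, bidirectional slope and duration criteria applied to the
#' robust-z of the potential-gradient channels.
#'
#' @param amp_threshold amplitude threshold in robust z units (default 4).
#' @param min_rise_slope,min_fall_slope minimum rising / falling slope
#'   within a candidate run, robust z per ms (default 0.5).
#' @param min_duration_ms,max_duration_ms event duration bounds (default
#'   20 / 200 ms).
#' @param merge_gap_ms supra-threshold runs on one channel closer than this
#'   are merged into one event (default 50).
#' @param cross_channel_window_ms per-channel events within this window are
#'   collapsed to one discharge (default 25).
#' @return list of class `detector_params`.
#' @export
detector_params <- function(amp_threshold = 4, min_rise_slope = 0.5,
                            min_fall_slope = 0.5, min_duration_ms = 20,
                            max_duration_ms = 200, merge_gap_ms = 50,
                            cross_channel_window_ms = 25) {
  if (amp_threshold <= 0 || min_rise_slope <= 0 || min_fall_slope <= 0)
    rlang::abort("thresholds must be > 0.", class = "ictalcsd_param_error")
  if (min_duration_ms >= max_duration_ms)
    rlang::abort("min_duration_ms must be below max_duration_ms.",
                 class = "ictalcsd_param_error")
  structure(list(amp_threshold = amp_threshold,
                 min_rise_slope = min_rise_slope,
                 min_fall_slope = min_fall_slope,
                 min_duration_ms = min_duration_ms,
                 max_duration_ms = max_duration_ms,
                 merge_gap_ms = merge_gap_ms,
                 cross_channel_window_ms = cross_channel_window_ms),
            class = "detector_params")
}

# Per-channel candidate events on one z trace. Returns tibble
# (peak_idx, peak_z, start_idx, end_idx).
channel_events <- function(z, fs, params) {
  hit <- abs(z) > params$amp_threshold
  if (!any(hit)) return(NULL)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than merge_gap
  gap <- params$merge_gap_ms / 1000 * fs
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[k, 1] - last[2] < gap) {
        keep[[length(keep)]] <- c(last[1], runs[k, 2])
      } else keep[[length(keep) + 1]] <- runs[k, ]
    }
    runs <- do.call(rbind, keep)
  }
  ms_per_sample <- 1000 / fs
  out <- lapply(seq_len(nrow(runs)), function(k) {
    i0 <- runs[k, 1]; i1 <- runs[k, 2]
    dur_ms <- (i1 - i0 + 1) * ms_per_sample
    if (dur_ms < params$min_duration_ms || dur_ms > params$max_duration_ms)
      return(NULL)
    seg <- z[i0:i1]
    dz <- diff(seg) / ms_per_sample
    if (!length(dz)) return(NULL)
    if (max(dz) < params$min_rise_slope) return(NULL)
    if (-min(dz) < params$min_fall_slope) return(NULL)
    pk <- which.max(abs(seg))
    c(peak_idx = i0 + pk - 1, peak_z = seg[pk], start_idx = i0, end_idx = i1)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) NULL else as.data.frame(out)
}

#' Detect ictal discharges
#'
#' Detection runs on the potential-gradient channels (monopolar recordings
#' are differentiated internally), mirroring differential laminar
#' acquisition. Each channel is converted to a robust z against its
#' pre-ictal baseline (median/MAD over the `"preictal"` annotation);
#' candidate events are maximal supra-threshold runs that satisfy rising
#' and falling slope thresholds and the duration bounds; runs closer than
#' `merge_gap_ms` are merged; per-channel events within
#' `cross_channel_window_ms` are collapsed into one discharge timed at the
#' median per-channel peak, with the peak channel at the largest |z|.
#'
#' @param rec a [laminar_recording()], preprocessed.
#' @param params a [detector_params()].
#' @return object of class `discharge_set`: `events` tibble (`time_s`,
#'   `duration_ms`, `peak_channel` (gradient channel index), `peak_z`,
#'   `n_channels` participating), plus the parameters used.
#' @export
detect_discharges <- function(rec, params = detector_params()) {
  base_iv <- annotation_interval(rec, "preictal")
  g <- if (rec$signal_kind == "gradient") rec$lfp else diff(rec$lfp)
  fs <- rec$fs_lfp_hz
  bi <- interval_samples(base_iv, fs, ncol(g))
  base <- g[, bi[1]:bi[2], drop = FALSE]
  med <- apply(base, 1, stats::median)
  sdv <- apply(base, 1, robust_sd)
  sdv[sdv == 0] <- Inf  # silent channels never fire
  per_ch <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    z <- (g[i, ] - med[i]) / sdv[i]
    ev <- channel_events(z, fs, params)
    if (!is.null(ev)) {
      ev$channel <- i
      per_ch[[i]] <- ev
    }
  }
  allev <- do.call(rbind, per_ch)
  if (is.null(allev) || !nrow(allev)) {
    events <- tibble::tibble(time_s = numeric(), duration_ms = numeric(),
                             peak_channel = integer(), peak_z = numeric(),
                             n_channels = integer())
    return(structure(list(events = events, params = params, fs_hz = fs),
                     class = "discharge_set"))
  }
  allev <- allev[order(allev$peak_idx), ]
  win <- params$cross_channel_window_ms / 1000 * fs
  grp <- cumsum(c(1, diff(allev$peak_idx) > win))
  agg <- lapply(split(allev, grp), function(d) {
    j <- which.max(abs(d$peak_z))
    tibble::tibble(
      time_s = (stats::median(d$peak_idx) - 1) / fs,
      duration_ms = max(d$end_idx - d$start_idx + 1) * 1000 / fs,
      peak_channel = d$channel[j],
      peak_z = d$peak_z[j],
      n_channels = nrow(d))
  })
  events <- dplyr::arrange(dplyr::bind_rows(agg), .data$time_s)
  # The merge-gap rule also applies across collapsed discharges: detections
  # closer than merge_gap_ms belong to one discharge (e.g. a late lobe of
  # the same event); the strongest detection represents the discharge.
  if (nrow(events) > 1) {
    gap_s <- params$merge_gap_ms / 1000
    grp2 <- integer(nrow(events)); grp2[1] <- 1L
    last_t <- events$time_s[1]
    for (k in 2:nrow(events)) {
      if (events$time_s[k] - last_t < gap_s) {
        grp2[k] <- grp2[k - 1]
      } else {
        grp2[k] <- grp2[k - 1] + 1L
      }
      last_t <- events$time_s[k]
    }
    events <- dplyr::bind_rows(lapply(split(events, grp2), function(dd) {
      j <- which.max(abs(dd$peak_z))
      out <- dd[j, ]
      out$n_channels <- max(dd$n_channels)
      out
    }))
    events <- dplyr::arrange(events, .data$time_s)
  }
  structure(list(events = events, params = params, fs_hz = fs),
            class = "discharge_set")
}

#' @export
print.discharge_set <- function(x, ...) {
  cat(sprintf("<discharge_set> %d events\n", nrow(x$events)))
  if (nrow(x$events)) print(utils::head(x$events, 5))
  invisible(x)
}

#' Score detections against ground truth
#'
#' Sensitivity uses greedy one-to-one nearest-neighbour matching within
#' `tol_ms`. Specificity is defined binwise (a point process has no native
#' true negatives): over bins of `bin_ms` spanning the recording, bins with
#' no true event are negatives, and a negative bin containing a detection is
#' a false positive. Precision (matched fraction of detections) and false
#' positives per minute are also reported.
#'
#' @param detected numeric vector of detected times (s) or a `discharge_set`.
#' @param truth numeric vector of true event times (s).
#' @param tol_ms matching tolerance (default 50).
#' @param bin_ms specificity bin width (default 100).
#' @param duration_s recording duration; inferred from the data if omitted.
#' @return tibble with `sensitivity`, `specificity`, `precision`,
#'   `false_per_min`, `n_true`, `n_detected`, `n_matched`.
#' @export
evaluate_detection <- function(detected, truth, tol_ms = 50, bin_ms = 100,
                               duration_s = NULL) {
  if (tol_ms <= 0) rlang::abort("tol_ms must be > 0.",
                                class = "ictalcsd_param_error")
  if (inherits(detected, "discharge_set")) detected <- detected$events$time_s
  tol <- tol_ms / 1000
  if (is.null(duration_s))
    duration_s <- max(c(detected, truth, 0)) + tol
  n_t <- length(truth); n_d <- length(detected)
  matched <- 0L
  if (n_t && n_d) {
    pairs <- expand.grid(d = seq_len(n_d), t = seq_len(n_t))
    pairs$dist <- abs(detected[pairs$d] - truth[pairs$t])
    pairs <- pairs[pairs$dist <= tol, ]
    pairs <- pairs[order(pairs$dist), ]
    used_d <- logical(n_d); used_t <- logical(n_t)
    for (k in seq_len(nrow(pairs))) {
      if (!used_d[pairs$d[k]] && !used_t[pairs$t[k]]) {
        used_d[pairs$d[k]] <- TRUE; used_t[pairs$t[k]] <- TRUE
        matched <- matched + 1L
      }
    }
    unmatched_d <- detected[!used_d]
  } else {
    unmatched_d <- detected
  }
  bw <- bin_ms / 1000
  n_bins <- max(1L, ceiling(duration_s / bw))
  t_bins <- unique(pmin(floor(truth / bw) + 1L, n_bins))
  d_bins <- unique(pmin(floor(unmatched_d / bw) + 1L, n_bins))
  neg_bins <- setdiff(seq_len(n_bins), t_bins)
  fp_bins <- intersect(d_bins, neg_bins)
  specificity <- if (length(neg_bins)) {
    (length(neg_bins) - length(fp_bins)) / length(neg_bins)
  } else NA_real_
  tibble::tibble(
    sensitivity = if (n_t) matched / n_t else NA_real_,
    specificity = specificity,
    precision = if (n_d) matched / n_d else NA_real_,
    false_per_min = (n_d - matched) / (duration_s / 60),
    n_true = n_t, n_detected = n_d, n_matched = matched,
    n_negative_bins = length(neg_bins), n_fp_bins = length(fp_bins))
}
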