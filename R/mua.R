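#' Estimate multi-unit firing rates from the MUA band
#'
#' Spiking is quantified by threshold-crossing counting (no spike sorting):
#' on each high-pass-filtered MUA channel, samples where |signal| exceeds
#' `k_mad` robust SDs start a crossing, successive crossings are separated
#' by at least the refractory period, counts are binned and smoothed with a
#' boxcar, and rates are min-max normalized to [0, 1] (per recording by
#' default, per channel optionally). Baseline mean and SD per channel come
#' from the pre-ictal annotation.
#'
#' @param rec a [laminar_recording()] with an MUA band present (high-pass
#'   filtered; see [filter_bands()]).
#' @param k_mad threshold in robust SD units (default 4).
#' @param refractory_ms minimum separation between counted crossings
#'   (default 1).
#' @param bin_ms rate bin width (default 10).
#' @param smooth_ms boxcar smoothing window (default 100).
#' @param normalize `"recording"`, `"per_channel"` or `"none"`.
#' @return object of class `mua_rate`: `rates` (contacts x bins), `bin_ms`,
#'   `t_s` bin centres, `baseline` tibble (`contact`, `mean`, `sd`),
#'   `annotations`, `spike_times` (list per contact).
#' @export
estimate_mua_rate <- function(rec, k_mad = 4, refractory_ms = 1, bin_ms = 10,
                              smooth_ms = 100,
                              normalize = c("recording", "per_channel", "none")) {
  normalize <- match.arg(normalize)
  if (is.null(rec$mua))
    rlang::abort("recording has no MUA band: firing rates cannot be analysed.",
                 class = "ictalcsd_capability_error")
  fs <- rec$fs_mua_hz
  nch <- nrow(rec$mua)
  total_s <- ncol(rec$mua) / fs
  n_bins <- floor(total_s * 1000 / bin_ms)
  bin_w <- bin_ms / 1000
  refr <- round(refractory_ms / 1000 * fs)
  rates <- matrix(0, nch, n_bins)
  spikes <- vector("list", nch)
  for (i in seq_len(nch)) {
    x <- rec$mua[i, ]
    thr <- k_mad * robust_sd(x)
    hit <- which(abs(x) > thr)
    if (length(hit)) {
      # onset samples of crossings, with refractory enforcement
      onset <- hit[c(TRUE, diff(hit) > 1)]
      if (length(onset) > 1)
        onset <- onset[c(TRUE, diff(onset) >= refr)]
      st <- (onset - 1) / fs
      spikes[[i]] <- st
      b <- pmin(floor(st / bin_w) + 1L, n_bins)
      tab <- tabulate(b, nbins = n_bins)
      rates[i, ] <- tab / bin_w
    } else spikes[[i]] <- numeric(0)
  }
  k <- max(1L, round(smooth_ms / bin_ms))
  if (k > 1) {
    kern <- rep(1 / k, k)
    rates <- t(apply(rates, 1, function(r)
      stats::filter(r, kern, sides = 2, circular = FALSE)))
    rates[is.na(rates)] <- 0
  }
  if (normalize == "recording") {
    rng <- range(rates)
    if (diff(rng) > 0) rates <- (rates - rng[1]) / diff(rng)
  } else if (normalize == "per_channel") {
    for (i in seq_len(nch)) {
      rng <- range(rates[i, ])
      if (diff(rng) > 0) rates[i, ] <- (rates[i, ] - rng[1]) / diff(rng)
    }
  }
  t_s <- (seq_len(n_bins) - 0.5) * bin_w
  baseline <- tibble::tibble(contact = seq_len(nch),
                             mean = NA_real_, sd = NA_real_)
  ann <- rec$annotations
  if (any(ann$name == "preictal")) {
    iv <- annotation_interval(rec, "preictal")
    sel <- t_s >= iv[1] & t_s < iv[2]
    baseline$mean <- rowMeans(rates[, sel, drop = FALSE])
    baseline$sd <- apply(rates[, sel, drop = FALSE], 1, stats::sd)
  }
  structure(list(rates = rates, bin_ms = bin_ms, t_s = t_s,
                 baseline = baseline, annotations = ann,
                 spike_times = spikes, normalized = normalize),
            class = "mua_rate")
}

#' @export
print.mua_rate <- function(x, ...) {
  cat(sprintf("<mua_rate> %d contacts x %d bins (%g ms), normalization: %s\n",
              nrow(x$rates), ncol(x$rates), x$bin_ms, x$normalized))
  invisible(x)
}

#' Fraction of ictal firing carried by the deepest channels
#'
#' Per channel, the baseline mean rate is subtracted from the mean ictal
#' rate and negative excesses are floored at zero; the statistic is the
#' summed excess over the deepest `ceiling(deepest_fraction * n)` channels
#' divided by the summed excess over all channels.
#'
#' @param mua a `mua_rate` with baseline and a `"seizure"` annotation.
#' @param deepest_fraction fraction of channels, from the deepest up,
#'   in (0, 1] (default 0.2).
#' @param ictal_interval optional numeric `c(start_s, end_s)` overriding the
#'   `"seizure"` annotation.
#' @return proportion in [0, 1].
#' @export
depth_fraction <- function(mua, deepest_fraction = 0.2, ictal_interval = NULL) {
  if (deepest_fraction <= 0 || deepest_fraction > 1)
    rlang::abort("deepest_fraction must be in (0, 1].",
                 class = "ictalcsd_param_error")
  if (is.null(ictal_interval)) {
    a <- mua$annotations[mua$annotations$name == "seizure", ]
    if (!nrow(a)) rlang::abort("no 'seizure' annotation.",
                               class = "ictalcsd_baseline_error")
    ictal_interval <- c(a$start_s[[1]], a$end_s[[1]])
  }
  sel <- mua$t_s >= ictal_interval[1] & mua$t_s < ictal_interval[2]
  excess <- rowMeans(mua$rates[, sel, drop = FALSE]) - mua$baseline$mean
  excess <- pmax(excess, 0)
  n <- nrow(mua$rates)
  k <- ceiling(deepest_fraction * n)
  deep <- (n - k + 1):n
  tot <- sum(excess)
  if (tot == 0) return(0)
  clamp01(sum(excess[deep]) / tot)
}
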