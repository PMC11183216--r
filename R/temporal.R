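#' Normalize a seizure to 100 time bins
#'
#' Partitions the seizure interval into `n_bins` equal-duration bins (the
#' last bin absorbs the remainder) and returns the mean |CSD| per contact
#' and bin, making seizures of different durations comparable on a common
#' normalized time axis.
#'
#' @param csd a `csd_matrix`.
#' @param interval seizure interval `c(start_s, end_s)`; defaults to the
#'   `"seizure"` annotation.
#' @param n_bins number of bins (default 100).
#' @return object of class `binned_csd`: `values` (channels x n_bins mean
#'   |CSD|), `bin_dur_s`, `channels`, `interval`.
#' @export
normalize_seizure_time <- function(csd, interval = NULL, n_bins = 100) {
  if (is.null(interval)) {
    a <- csd$annotations[csd$annotations$name == "seizure", ]
    if (!nrow(a)) rlang::abort("no 'seizure' annotation.")
    interval <- c(a$start_s[[1]], a$end_s[[1]])
  }
  iv <- interval_samples(interval, csd$fs_hz, ncol(csd$values))
  n_samp <- iv[2] - iv[1] + 1
  if (n_samp < n_bins)
    rlang::abort(sprintf(
      "seizure interval holds %d samples, fewer than %d bins.", n_samp, n_bins),
      class = "ictalcsd_resolution_error")
  spb <- n_samp %/% n_bins  # samples per bin; last bin absorbs the remainder
  vals <- matrix(0, nrow(csd$values), n_bins)
  av <- abs(csd$values)
  for (b in seq_len(n_bins)) {
    j0 <- iv[1] + (b - 1) * spb
    j1 <- if (b == n_bins) iv[2] else iv[1] + b * spb - 1
    vals[, b] <- rowMeans(av[, j0:j1, drop = FALSE])
  }
  structure(list(values = vals, bin_dur_s = (n_samp / csd$fs_hz) / n_bins,
                 channels = csd$channels, interval = interval,
                 fs_hz = csd$fs_hz),
            class = "binned_csd")
}

#' Baseline |CSD| statistics for engagement analysis
#'
#' Bins the pre-ictal |CSD| at the same bin duration as the ictal bins and
#' returns the per-contact mean and SD of the bin means.
#'
#' @param csd a `csd_matrix`.
#' @param bin_dur_s ictal bin duration (from [normalize_seizure_time()]).
#' @param interval baseline interval; defaults to the `"preictal"`
#'   annotation (which must span at least 10 s).
#' @return tibble (`contact`, `mean`, `sd`).
#' @export
engagement_baseline <- function(csd, bin_dur_s, interval = NULL) {
  if (is.null(interval)) {
    a <- csd$annotations[csd$annotations$name == "preictal", ]
    if (!nrow(a)) rlang::abort("no 'preictal' annotation.",
                               class = "ictalcsd_baseline_error")
    interval <- c(a$start_s[[1]], a$end_s[[1]])
  }
  if (diff(interval) < 10)
    rlang::abort("baseline must span at least 10 s of pre-ictal data.",
                 class = "ictalcsd_baseline_error")
  iv <- interval_samples(interval, csd$fs_hz, ncol(csd$values))
  spb <- max(1L, round(bin_dur_s * csd$fs_hz))
  n_b <- (iv[2] - iv[1] + 1) %/% spb
  if (n_b < 2) rlang::abort("baseline shorter than two bins.")
  av <- abs(csd$values)
  bm <- vapply(seq_len(n_b), function(b) {
    cols <- (iv[1] + (b - 1) * spb):(iv[1] + b * spb - 1)
    rowMeans(av[, cols, drop = FALSE])
  }, numeric(nrow(av)))
  tibble::tibble(contact = csd$channels, mean = rowMeans(bm),
                 sd = apply(bm, 1, stats::sd))
}

#' Engagement matrix over normalized seizure time
#'
#' Per contact and bin, engagement is the thresholded excess
#' `max(0, bin - (baseline mean + sd_mult * baseline sd))` — the amount by
#' which the bin's mean |CSD| deviates beyond `sd_mult` SDs from baseline
#' (`binary = TRUE` counts outlier bins as 0/1 instead). Contacts are
#' optionally aggregated (summed) into layer groups, and each bin is then
#' normalized to a distribution across contacts/groups; all-zero bins stay
#' zero.
#'
#' @param binned a `binned_csd` from [normalize_seizure_time()].
#' @param baseline tibble from [engagement_baseline()].
#' @param sd_mult outlier threshold in baseline SDs (default 2).
#' @param partition optional [layer_partition()]; when given, rows are the
#'   three layer groups.
#' @param binary logical: strict outlier counting instead of excess.
#' @return object of class `engagement_matrix`: `values` (rows x 100),
#'   `rows` (contact indices or group names), `raw_excess` (same shape,
#'   before per-bin normalization).
#' @export
engagement_matrix <- function(binned, baseline, sd_mult = 2,
                              partition = NULL, binary = FALSE) {
  if (is.null(baseline) || !all(c("mean", "sd") %in% names(baseline)))
    rlang::abort("missing baseline.", class = "ictalcsd_baseline_error")
  thr <- baseline$mean + sd_mult * baseline$sd
  exc <- pmax(binned$values - thr, 0)
  if (binary) exc <- (exc > 0) * 1
  rows <- binned$channels
  if (!is.null(partition)) {
    groups <- levels(partition$group)
    agg <- matrix(0, length(groups), ncol(exc),
                  dimnames = list(groups, NULL))
    for (g in groups) {
      sel <- which(binned$channels %in%
                     partition$contact[partition$group == g])
      if (length(sel))
        agg[g, ] <- colSums(exc[sel, , drop = FALSE])
    }
    exc_agg <- agg
    rows <- groups
  } else exc_agg <- exc
  norm <- exc_agg
  cs <- colSums(exc_agg)
  nz <- cs > 0
  norm[, nz] <- sweep(exc_agg[, nz, drop = FALSE], 2, cs[nz], "/")
  structure(list(values = norm, raw_excess = exc_agg, rows = rows,
                 sd_mult = sd_mult, binary = binary,
                 bin_dur_s = binned$bin_dur_s),
            class = "engagement_matrix")
}

#' @export
print.engagement_matrix <- function(x, ...) {
  cat(sprintf("<engagement_matrix> %d rows x %d bins (%.2f s/bin)\n",
              nrow(x$values), ncol(x$values), x$bin_dur_s))
  invisible(x)
}

#' Engagement onset in normalized seizure time
#'
#' Change-point scan over a 100-bin engagement series: every split
#' `k in [min_seg, 100 - min_seg]` is scored with a Welch t test of bins
#' `<= k` against bins `> k`; among significant splits with a late-segment
#' increase, the split with the largest t statistic is taken and the onset
#' is the first bin of its late segment. Returns onset `NA` when no split
#' is significant (e.g. a constant series).
#'
#' @param series numeric vector (one engagement row, typically length 100).
#' @param alpha significance level (default 0.01).
#' @param min_seg minimum segment length in bins (default 5).
#' @return tibble (`onset`, `p_value`, `statistic`, `mean_early`,
#'   `mean_late`); `onset` in bins = percent of normalized seizure time.
#' @export
engagement_onset <- function(series, alpha = 0.01, min_seg = 5) {
  n <- length(series)
  ks <- seq.int(min_seg, n - min_seg)
  best <- NULL
  for (k in ks) {
    w <- welch_t(series[1:k], series[(k + 1):n])
    if (w$p.value < alpha && w$mean_late > w$mean_early) {
      if (is.null(best) || w$statistic > best$statistic) {
        best <- w; best$k <- k
      }
    }
  }
  if (is.null(best))
    return(tibble::tibble(onset = NA_real_, p_value = NA_real_,
                          statistic = NA_real_, mean_early = NA_real_,
                          mean_late = NA_real_))
  tibble::tibble(onset = best$k + 1, p_value = best$p.value,
                 statistic = best$statistic, mean_early = best$mean_early,
                 mean_late = best$mean_late)
}
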