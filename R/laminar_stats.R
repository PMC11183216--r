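#' Contact-to-layer-group partition
#'
#' Maps contact indices (1 = most superficial) to the three canonical layer
#' groups. The default for a 24-contact, 150-um-pitch array assigns
#' contacts 1-10 to the supragranular (layers I-III), 11-13 to the granular
#' (layer IV) and 14-24 to the infragranular (layers V-VI) group,
#' approximating human neocortical layer proportions; the boundaries are
#' fully configurable.
#'
#' @param n_contacts number of contacts (default 24).
#' @param granular_start,granular_end first and last granular contact
#'   (defaults 11 and 13).
#' @return tibble (`contact`, `group`) with `group` an ordered factor
#'   `supragranular < granular < infragranular`.
#' @export
layer_partition <- function(n_contacts = 24, granular_start = 11,
                            granular_end = 13) {
  if (!(granular_start > 1 && granular_end >= granular_start &&
        granular_end < n_contacts))
    rlang::abort("granular band must be interior and ordered.")
  grp <- rep("infragranular", n_contacts)
  grp[seq_len(granular_start - 1)] <- "supragranular"
  grp[granular_start:granular_end] <- "granular"
  tibble::tibble(
    contact = seq_len(n_contacts),
    group = factor(grp, levels = c("supragranular", "granular",
                                   "infragranular"), ordered = TRUE))
}

# map a csd_matrix row index to its contact number
csd_contact_of_row <- function(csd, row) csd$channels[row]

#' Peak-layer counts for detected discharges
#'
#' For each event, the contact with the largest |CSD| in a window of
#' `win_ms` around the event peak is assigned to its layer group; ties go
#' to the deepest tied contact (deterministic rule).
#'
#' @param csd a `csd_matrix`.
#' @param events numeric vector of event times (s) or a `discharge_set`.
#' @param partition a [layer_partition()].
#' @param win_ms half-window around the event peak (default 25).
#' @return tibble (`group`, `n`); counts sum to the number of usable events.
#' @export
peak_layer_counts <- function(csd, events, partition = layer_partition(),
                              win_ms = 25) {
  if (inherits(events, "discharge_set")) events <- events$events$time_s
  groups <- levels(partition$group)
  counts <- stats::setNames(rep(0L, 3), groups)
  n_samp <- ncol(csd$values)
  for (tv in events) {
    i0 <- max(1L, round((tv - win_ms / 1000) * csd$fs_hz) + 1L)
    i1 <- min(n_samp, round((tv + win_ms / 1000) * csd$fs_hz) + 1L)
    if (i1 < i0) next
    seg <- abs(csd$values[, i0:i1, drop = FALSE])
    mx <- apply(seg, 1, max)
    row <- max(which(mx == max(mx)))     # deepest tied contact wins
    g <- as.character(partition$group[partition$contact ==
                                        csd_contact_of_row(csd, row)])
    counts[g] <- counts[g] + 1L
  }
  tibble::tibble(group = factor(groups, levels = groups, ordered = TRUE),
                 n = as.integer(counts))
}

#' Chi-square test of peak-layer distribution between zones
#'
#' Pearson chi-square (df = 2) on the 2 x 3 table of peak-layer counts in
#' the onset zone versus outside it. When any expected cell count falls
#' below 5 the exact test is used instead, with a warning.
#'
#' @param counts_onset,counts_outside length-3 count vectors (supragranular,
#'   granular, infragranular) or `peak_layer_counts()` tibbles.
#' @return tibble (`statistic`, `df`, `p_value`, `method`).
#' @export
zone_layer_chi2 <- function(counts_onset, counts_outside) {
  cv <- function(x) if (is.data.frame(x)) x$n else x
  tab <- rbind(onset = cv(counts_onset), outside = cv(counts_outside))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    rlang::abort("zero-margin row or column: degenerate table.",
                 class = "ictalcsd_degenerate_error")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    rlang::warn("expected cell count < 5: falling back to the exact test.")
    ft <- stats::fisher.test(tab)
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p_value = ft$p.value, method = "fisher"))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, method = "pearson")
}

#' Sink/source statistics per layer group across recordings
#'
#' For each normalized CSD matrix, the mean and variance of the positive
#' values (sinks) and of the negative values (sources) are computed per
#' layer group over the ictal interval; Welch two-sample t-tests then
#' compare the zone-characteristic group (infragranular + granular for the
#' onset zone, supragranular for propagation) against the remaining groups
#' across recordings.
#'
#' @param csd_list list of normalized `csd_matrix` objects (one per
#'   recording/seizure), all with a `"seizure"` annotation.
#' @param partition a [layer_partition()].
#' @param zone `"onset"` or `"propagation"`: selects the zone-characteristic
#'   group for the tests.
#' @return list of class `layer_stats_report`: `per_recording` tibble
#'   (`recording`, `group`, `polarity`, `mean`, `variance`, `n_values`),
#'   `tests` tibble (`polarity`, `measure`, `characteristic_mean`,
#'   `other_mean`, `t`, `p_value`), and `zone`.
#' @export
sink_source_layer_stats <- function(csd_list, partition = layer_partition(),
                                    zone = c("onset", "propagation")) {
  zone <- match.arg(zone)
  if (inherits(csd_list, "csd_matrix")) csd_list <- list(csd_list)
  per <- purrr::imap(csd_list, function(csd, r) {
    if (csd$normalized == "raw")
      rlang::abort("CSD must be normalized (rescale_sinks_sources()).")
    cols <- seq_len(ncol(csd$values))
    if (!is.null(csd$annotations) && any(csd$annotations$name == "seizure")) {
      a <- csd$annotations[csd$annotations$name == "seizure", ]
      ivs <- interval_samples(c(a$start_s[[1]], a$end_s[[1]]), csd$fs_hz,
                              ncol(csd$values))
      cols <- ivs[1]:ivs[2]
    }
    purrr::map_dfr(levels(partition$group), function(g) {
      rows <- which(csd$channels %in%
                      partition$contact[partition$group == g])
      if (!length(rows)) {
        rlang::warn(sprintf("group %s has no contacts: skipped.", g))
        return(NULL)
      }
      v <- csd$values[rows, cols, drop = FALSE]
      pos <- v[v > 0]; neg <- v[v < 0]
      tibble::tibble(
        recording = r, group = g,
        polarity = c("sink", "source"),
        mean = c(mean(pos), mean(neg)),
        variance = c(stats::var(pos), stats::var(neg)),
        n_values = c(length(pos), length(neg)))
    })
  })
  per <- dplyr::bind_rows(per)
  char_groups <- if (zone == "onset") c("granular", "infragranular")
                 else "supragranular"
  tests <- purrr::map_dfr(c("sink", "source"), function(pol) {
    purrr::map_dfr(c("mean", "variance"), function(meas) {
      d <- per[per$polarity == pol, ]
      x <- tapply(d[[meas]][d$group %in% char_groups],
                  d$recording[d$group %in% char_groups], mean)
      y <- tapply(d[[meas]][!d$group %in% char_groups],
                  d$recording[!d$group %in% char_groups], mean)
      if (length(x) >= 2 && length(y) >= 2) {
        # Welch test, tolerant of degenerate (zero-variance) samples
        tt <- welch_t(y, x)   # statistic > 0: characteristic group larger
        tibble::tibble(polarity = pol, measure = meas,
                       characteristic_mean = mean(x), other_mean = mean(y),
                       t = tt$statistic, p_value = tt$p.value)
      } else {
        tibble::tibble(polarity = pol, measure = meas,
                       characteristic_mean = mean(x), other_mean = mean(y),
                       t = NA_real_, p_value = NA_real_)
      }
    })
  })
  structure(list(per_recording = per, tests = tests, zone = zone,
                 characteristic_groups = char_groups),
            class = "layer_stats_report")
}

#' @export
print.layer_stats_report <- function(x, ...) {
  cat(sprintf("<layer_stats_report> zone: %s (characteristic: %s)\n", x$zone,
              paste(x$characteristic_groups, collapse = " + ")))
  print(x$tests)
  invisible(x)
}

#' Sink-to-source alternation index
#'
#' Per contact: the fraction of events whose CSD changes sign between the
#' event time and `lag_ms` later. Events where |CSD| at the event time is
#' below the noise floor (`floor_mult` robust SDs of the pre-ictal CSD on
#' that contact) are excluded from that contact's denominator.
#'
#' @param csd a `csd_matrix` (raw or normalized) with a `"preictal"`
#'   annotation (or supply `baseline_interval`).
#' @param events event times (s) or a `discharge_set`.
#' @param lag_ms alternation lag (default 50).
#' @param floor_mult noise-floor multiplier (default 1).
#' @param baseline_interval optional numeric `c(start_s, end_s)`.
#' @return tibble (`contact`, `index`, `n_events`); `index` is `NA` on
#'   contacts with an empty denominator.
#' @export
alternation_index <- function(csd, events, lag_ms = 50, floor_mult = 1,
                              baseline_interval = NULL) {
  if (inherits(events, "discharge_set")) events <- events$events$time_s
  if (is.null(baseline_interval)) {
    a <- csd$annotations[csd$annotations$name == "preictal", ]
    if (!nrow(a)) rlang::abort("no 'preictal' annotation for the noise floor.",
                               class = "ictalcsd_baseline_error")
    baseline_interval <- c(a$start_s[[1]], a$end_s[[1]])
  }
  n_samp <- ncol(csd$values)
  bi <- interval_samples(baseline_interval, csd$fs_hz, n_samp)
  floorv <- floor_mult *
    apply(csd$values[, bi[1]:bi[2], drop = FALSE], 1, robust_sd)
  i_ev <- round(events * csd$fs_hz) + 1L
  i_lag <- i_ev + round(lag_ms / 1000 * csd$fs_hz)
  ok <- i_ev >= 1 & i_lag <= n_samp
  if (!any(ok))
    rlang::abort("no event has room for the lag: empty denominator.",
                 class = "ictalcsd_degenerate_error")
  i_ev <- i_ev[ok]; i_lag <- i_lag[ok]
  nch <- nrow(csd$values)
  idx <- rep(NA_real_, nch); nev <- integer(nch)
  for (i in seq_len(nch)) {
    v0 <- csd$values[i, i_ev]
    v1 <- csd$values[i, i_lag]
    use <- abs(v0) >= floorv[i]
    nev[i] <- sum(use)
    if (nev[i] > 0) idx[i] <- mean(sign(v0[use]) != sign(v1[use]))
  }
  tibble::tibble(contact = csd$channels, index = idx, n_events = nev)
}
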