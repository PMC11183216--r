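# broom-style tidiers for the package's result objects.

#' Tidy a CSD matrix into long form
#'
#' @param x a `csd_matrix`.
#' @param downsample keep every `downsample`-th sample (default 1 = all).
#' @param ... unused.
#' @return tibble (`contact`, `time_s`, `csd`).
#' @method tidy csd_matrix
#' @export
tidy.csd_matrix <- function(x, downsample = 1, ...) {
  cols <- seq(1, ncol(x$values), by = downsample)
  tibble::tibble(
    contact = rep(x$channels, times = length(cols)),
    time_s = rep((cols - 1) / x$fs_hz, each = nrow(x$values)),
    csd = as.numeric(x$values[, cols]))
}

#' @method tidy discharge_set
#' @export
tidy.discharge_set <- function(x, ...) x$events

#' @method glance discharge_set
#' @export
glance.discharge_set <- function(x, ...) {
  tibble::tibble(n_events = nrow(x$events),
                 rate_hz = if (nrow(x$events) > 1)
                   nrow(x$events) / diff(range(x$events$time_s)) else NA_real_,
                 amp_threshold = x$params$amp_threshold)
}

#' @method tidy engagement_matrix
#' @export
tidy.engagement_matrix <- function(x, ...) {
  tibble::tibble(
    row = rep(x$rows, times = ncol(x$values)),
    bin = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    engagement = as.numeric(x$values))
}

#' @method tidy mua_rate
#' @export
tidy.mua_rate <- function(x, ...) {
  tibble::tibble(
    contact = rep(seq_len(nrow(x$rates)), times = ncol(x$rates)),
    time_s = rep(x$t_s, each = nrow(x$rates)),
    rate = as.numeric(x$rates))
}

#' @method tidy pattern_result
#' @export
tidy.pattern_result <- function(x, ...) x$assignment

#' @method glance pattern_result
#' @export
glance.pattern_result <- function(x, ...) {
  tibble::tibble(
    n_patterns = x$n_patterns,
    n_events = nrow(x$assignment),
    n_switches = length(x$switch_times_s),
    first_switch_s = if (length(x$switch_times_s))
      x$switch_times_s[1] else NA_real_)
}

#' @method tidy layer_stats_report
#' @export
tidy.layer_stats_report <- function(x, ...) x$per_recording

#' @method glance layer_stats_report
#' @export
glance.layer_stats_report <- function(x, ...) {
  tidyr::pivot_wider(x$tests[, c("polarity", "measure", "p_value")],
                     names_from = c("polarity", "measure"),
                     values_from = "p_value", names_prefix = "p_")
}

#' @export
generics::tidy

#' @export
generics::glance
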