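# ggplot2 visualisations. Depth is plotted increasing downwards, matching
# laminar convention (contact 1 = pial surface on top).

#' @method autoplot csd_matrix
#' @export
autoplot.csd_matrix <- function(object, interval = NULL, downsample = 4, ...) {
  d <- tidy.csd_matrix(object, downsample = downsample)
  if (!is.null(interval))
    d <- dplyr::filter(d, .data$time_s >= interval[1],
                       .data$time_s <= interval[2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$contact,
                                  fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "CSD") +
    ggplot2::labs(x = "time (s)", y = "contact (superficial → deep)",
                  title = "Current source density (sinks red, sources blue)")
}

#' @method autoplot engagement_matrix
#' @export
autoplot.engagement_matrix <- function(object, ...) {
  d <- tidy.engagement_matrix(object)
  d$row <- factor(d$row, levels = rev(unique(object$rows)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$row,
                                  fill = .data$engagement)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "engagement") +
    ggplot2::labs(x = "normalized seizure time (%)", y = NULL,
                  title = "Layer engagement over normalized seizure time")
}

#' @method autoplot mua_rate
#' @export
autoplot.mua_rate <- function(object, ...) {
  d <- tidy.mua_rate(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$contact,
                                  fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "rate") +
    ggplot2::labs(x = "time (s)", y = "contact (superficial → deep)",
                  title = "Normalized multi-unit firing rate")
}

#' Plot ICA pattern motifs
#'
#' One panel per identified pattern showing its mean laminar motif
#' (channels x window time).
#'
#' @param pr a `pattern_result`.
#' @param fs_hz sampling rate of the windows, for the time axis.
#' @return a ggplot object.
#' @export
plot_pattern_motifs <- function(pr, fs_hz = 2000) {
  if (!pr$n_patterns) rlang::abort("no patterns to plot.")
  d <- purrr::map_dfr(seq_len(pr$n_patterns), function(k) {
    m <- pr$patterns[[k]]$motif
    tibble::tibble(
      pattern = paste("pattern", k),
      contact = rep(seq_len(nrow(m)), times = ncol(m)),
      time_s = rep((seq_len(ncol(m)) - 1) / fs_hz - ncol(m) / fs_hz / 2,
                   each = nrow(m)),
      csd = as.numeric(m))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$contact,
                                  fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "CSD") +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(x = "time from discharge peak (s)",
                  y = "contact (superficial → deep)")
}

#' @importFrom rlang .data
#' @export
ggplot2::autoplot
NULL
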