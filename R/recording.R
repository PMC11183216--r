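#' Laminar recording container
#'
#' Bundles the low-frequency field-potential band (LFP) and, optionally, the
#' high-frequency multi-unit band (MUA) of a laminar microelectrode recording
#' together with its geometry and annotations. Contact 1 is the most
#' superficial contact; depth increases with the row index.
#'
#' @param lfp numeric matrix, contacts x samples (uV). With
#'   `signal_kind = "gradient"` the matrix holds successive-contact
#'   differences and has `n_contacts - 1` rows.
#' @param fs_lfp_hz LFP sampling rate (Hz).
#' @param mua optional numeric matrix, contacts x samples (uV), high band.
#' @param fs_mua_hz MUA sampling rate (Hz); required when `mua` is given.
#' @param spacing_um inter-contact spacing (micrometres).
#' @param signal_kind `"monopolar"` or `"gradient"`.
#' @param zone `"onset"`, `"propagation"` or `"unknown"`.
#' @param line_freq_hz mains frequency of the recording site (50 or 60).
#' @param annotations tibble with columns `name`, `start_s`, `end_s`; named
#'   intervals such as `"preictal"` and `"seizure"` in seconds from start.
#' @param channel_status character vector, `"good"`/`"bad"` per contact.
#'
#' @return An object of class `laminar_recording`.
#' @export
laminar_recording <- function(lfp, fs_lfp_hz, mua = NULL, fs_mua_hz = NULL,
                              spacing_um = 150, signal_kind = "monopolar",
                              zone = "unknown", line_freq_hz = 50,
                              annotations = NULL, channel_status = NULL) {
  if (!is.matrix(lfp)) rlang::abort("`lfp` must be a contacts x samples matrix.")
  if (!is.numeric(fs_lfp_hz) || fs_lfp_hz <= 0)
    rlang::abort("`fs_lfp_hz` must be a positive sampling rate.")
  signal_kind <- match.arg(signal_kind, c("monopolar", "gradient"))
  zone <- match.arg(zone, c("onset", "propagation", "unknown"))
  n_contacts <- nrow(lfp) + (signal_kind == "gradient")
  if (!is.null(mua)) {
    if (is.null(fs_mua_hz) || fs_mua_hz <= 0)
      rlang::abort("`fs_mua_hz` must be supplied (and positive) with `mua`.")
    if (nrow(mua) != n_contacts)
      rlang::abort("`mua` must have one row per contact.")
  }
  if (spacing_um <= 0) rlang::abort("`spacing_um` must be positive.")
  if (is.null(annotations)) {
    annotations <- tibble::tibble(name = character(), start_s = numeric(),
                                  end_s = numeric())
  }
  annotations <- tibble::as_tibble(annotations)
  dur <- ncol(lfp) / fs_lfp_hz
  if (nrow(annotations) &&
      any(annotations$start_s < 0 | annotations$end_s > dur + 1e-9 |
          annotations$start_s > annotations$end_s))
    rlang::abort("annotated intervals must lie within the recording.")
  if (is.null(channel_status)) channel_status <- rep("good", n_contacts)
  if (length(channel_status) != n_contacts)
    rlang::abort("`channel_status` needs one entry per contact.")
  structure(
    list(lfp = lfp, mua = mua, fs_lfp_hz = fs_lfp_hz, fs_mua_hz = fs_mua_hz,
         spacing_um = spacing_um, signal_kind = signal_kind, zone = zone,
         line_freq_hz = line_freq_hz, annotations = annotations,
         channel_status = channel_status, n_contacts = n_contacts),
    class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf("<laminar_recording> %d contacts (%s), %.1f s LFP @ %g Hz",
              x$n_contacts, x$signal_kind, ncol(x$lfp) / x$fs_lfp_hz,
              x$fs_lfp_hz))
  if (!is.null(x$mua))
    cat(sprintf(", MUA @ %g Hz", x$fs_mua_hz))
  cat(sprintf("\n  zone: %s; spacing %g um; line %g Hz\n",
              x$zone, x$spacing_um, x$line_freq_hz))
  if (nrow(x$annotations))
    cat("  annotations:",
        paste(sprintf("%s [%.1f, %.1f]", x$annotations$name,
                      x$annotations$start_s, x$annotations$end_s),
              collapse = ", "), "\n")
  invisible(x)
}

# Fetch one named annotation interval as c(start, end); error when missing.
annotation_interval <- function(rec, name) {
  a <- rec$annotations[rec$annotations$name == name, ]
  if (!nrow(a))
    rlang::abort(sprintf("recording lacks a '%s' annotation.", name),
                 class = "ictalcsd_baseline_error")
  c(a$start_s[[1]], a$end_s[[1]])
}

# Sample index range (LFP clock) for a [start, end] interval in seconds.
interval_samples <- function(interval, fs, n) {
  i0 <- max(1L, floor(interval[1] * fs) + 1L)
  i1 <- min(n, ceiling(interval[2] * fs))
  if (i1 < i0) rlang::abort("interval contains no samples.")
  c(i0, i1)
}
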