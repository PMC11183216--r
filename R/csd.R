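#' Current source density by second spatial differentiation
#'
#' `csd[i, t] = (phi[i-1, t] - 2 phi[i, t] + phi[i+1, t]) / h^2`, with sinks
#' positive: a local potential minimum in depth (current flowing into the
#' cells) yields a positive CSD. With `vaknin = TRUE` the potential is
#' padded with virtual channels above and below the array so the CSD is
#' defined on all `n` contacts (`edge_mode = "zeros"` pads zeros,
#' `"duplicate"` repeats the edge channels, the classical variant); with
#' `vaknin = FALSE` only the `n - 2` interior contacts are returned.
#' Optional spatial smoothing convolves each time point with a 5-point
#' Hamming window (`c(0.08, 0.54, 1, 0.54, 0.08) / 2.24`), truncated and
#' renormalized at the edges.
#'
#' @param rec a monopolar [laminar_recording()] (gradient input must be
#'   converted with [gradient_to_monopolar()] first) or a contacts x samples
#'   matrix.
#' @param vaknin logical (default TRUE).
#' @param smooth logical (default TRUE).
#' @param edge_mode `"zeros"` or `"duplicate"`.
#' @param spacing_um contact spacing; taken from the recording when omitted.
#' @param fs_hz sampling rate; taken from the recording when omitted.
#' @return object of class `csd_matrix`: fields `values` (channels x
#'   samples, arbitrary units, sinks positive), `spacing_um`, `fs_hz`,
#'   `smoothing`, `normalized`, `channels` (contact indices of the rows) and
#'   `annotations` (copied from the recording when available).
#' @export
compute_csd <- function(rec, vaknin = TRUE, smooth = TRUE,
                        edge_mode = c("zeros", "duplicate"),
                        spacing_um = NULL, fs_hz = NULL) {
  edge_mode <- match.arg(edge_mode)
  ann <- NULL
  if (inherits(rec, "laminar_recording")) {
    if (rec$signal_kind == "gradient")
      rlang::abort(
        "gradient recording: convert with gradient_to_monopolar() first.",
        class = "ictalcsd_state_error")
    phi <- rec$lfp
    spacing_um <- spacing_um %||% rec$spacing_um
    fs_hz <- fs_hz %||% rec$fs_lfp_hz
    ann <- rec$annotations
  } else {
    phi <- rec
    spacing_um <- spacing_um %||% 150
    fs_hz <- fs_hz %||% 1
  }
  n <- nrow(phi)
  if (n < 3) rlang::abort("CSD needs at least 3 contacts.")
  h <- spacing_um / 1000
  if (vaknin) {
    pad_top <- if (edge_mode == "zeros") 0 * phi[1, ] else phi[1, ]
    pad_bot <- if (edge_mode == "zeros") 0 * phi[n, ] else phi[n, ]
    phip <- rbind(pad_top, phi, pad_bot)
    rows <- seq_len(n)
  } else {
    phip <- phi
    rows <- seq_len(n - 2)
  }
  vals <- (phip[rows, , drop = FALSE] - 2 * phip[rows + 1, , drop = FALSE] +
             phip[rows + 2, , drop = FALSE]) / h^2
  channels <- if (vaknin) seq_len(n) else 2:(n - 1)
  if (smooth) vals <- hamming5_smooth(vals)
  structure(list(values = unname(vals), spacing_um = spacing_um, fs_hz = fs_hz,
                 smoothing = if (smooth) "hamming5" else "none",
                 normalized = "raw", channels = channels, annotations = ann),
            class = "csd_matrix")
}

# 5-point Hamming smoothing across channels, edge-truncated + renormalized.
hamming5_smooth <- function(vals) {
  w <- c(0.08, 0.54, 1, 0.54, 0.08) / 2.24
  n <- nrow(vals)
  out <- vals * 0
  for (i in seq_len(n)) {
    j <- (i - 2):(i + 2)
    ok <- j >= 1 & j <= n
    wi <- w[ok] / sum(w[ok])
    out[i, ] <- wi %*% vals[j[ok], , drop = FALSE]
  }
  out
}

#' @export
print.csd_matrix <- function(x, ...) {
  cat(sprintf("<csd_matrix> %d channels x %d samples @ %g Hz, smoothing: %s, %s\n",
              nrow(x$values), ncol(x$values), x$fs_hz, x$smoothing,
              x$normalized))
  invisible(x)
}

#' Rescale sinks to [0, 1] and sources to [-1, 0]
#'
#' Positive CSD values (sinks) are min-max rescaled to `[0, 1]` and negative
#' values (sources) are rescaled in magnitude to `[-1, 0]`, so the largest
#' sink maps to 1 and the strongest source to -1. The rescaling range is
#' taken over the chosen scope: the whole matrix jointly (default), per
#' channel, or restricted to a named annotated interval (e.g. the seizure).
#' `invert = TRUE` applies the inverted orientation
#' `1 + (X - min)/(max - min) * (0 - 1)` (min maps to 1) to each part.
#'
#' @param csd a `csd_matrix` with `normalized == "raw"`.
#' @param scope `"recording"` or `"per_channel"`.
#' @param interval optional annotation name (e.g. `"seizure"`) or numeric
#'   `c(start_s, end_s)` defining where the min/max are measured.
#' @param invert logical (default FALSE).
#' @return the rescaled `csd_matrix` (`normalized = "sink01_sourceneg1"`).
#' @export
rescale_sinks_sources <- function(csd, scope = c("recording", "per_channel"),
                                  interval = NULL, invert = FALSE) {
  scope <- match.arg(scope)
  if (csd$normalized != "raw")
    rlang::abort("csd is already normalized.")
  v <- csd$values
  cols <- seq_len(ncol(v))
  if (!is.null(interval)) {
    if (is.character(interval)) {
      a <- csd$annotations[csd$annotations$name == interval, ]
      if (!nrow(a)) rlang::abort(sprintf("no '%s' annotation.", interval))
      interval <- c(a$start_s[[1]], a$end_s[[1]])
    }
    cols <- interval_samples(interval, csd$fs_hz, ncol(v))
    cols <- cols[1]:cols[2]
  }
  if (all(v == 0)) {
    rlang::warn("CSD is identically zero: degenerate rescaling range.")
    csd$normalized <- "sink01_sourceneg1"
    return(csd)
  }
  rescale_part <- function(x, ref) {
    # x: values to map, ref: scope values; the part is the non-negative
    # range (zero participates, so {0, 2, 4} maps to {0, 0.5, 1})
    pos <- ref[ref >= 0]
    if (!length(pos) || max(pos) == 0) return(x * 0)
    lo <- min(pos); hi <- max(pos)
    if (hi == lo) return(ifelse(x > 0, 1, 0))
    out <- (x - lo) / (hi - lo)
    if (invert) out <- 1 - out
    clamp01(out) * (x > 0)
  }
  apply_scope <- function(mat, refmat) {
    p <- rescale_part(mat, refmat)
    ng <- -rescale_part(-mat, -refmat)
    p + ng
  }
  if (scope == "recording") {
    csd$values <- apply_scope(v, v[, cols, drop = FALSE])
  } else {
    for (i in seq_len(nrow(v)))
      csd$values[i, ] <- apply_scope(v[i, , drop = FALSE],
                                     v[i, cols, drop = FALSE])
  }
  csd$normalized <- "sink01_sourceneg1"
  csd
}
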