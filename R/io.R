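#' Write / read a laminar recording container
#'
#' HDF5 layout: datasets `/lfp`, `/mua` (channels x samples),
#' `/events/<name>` groups written by [write_events()], annotation table
#' under `/annotations`, scalar metadata as root attributes
#' (`fs_lfp_hz`, `fs_mua_hz`, `spacing_um`, `signal_kind`, `zone`,
#' `line_freq_hz`, `channel_status`, `container_version`). The roundtrip is
#' lossless for all fields.
#'
#' @param rec a [laminar_recording()].
#' @param path file path (`.h5`); overwritten if present.
#' @return `path`, invisibly (write); a [laminar_recording()] (read).
#' @export
write_recording <- function(rec, path) {
  if (!dir.exists(dirname(path)))
    rlang::abort("parent directory does not exist.")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$lfp, path, "lfp")
  if (!is.null(rec$mua)) rhdf5::h5write(rec$mua, path, "mua")
  rhdf5::h5write(as.data.frame(rec$annotations), path, "annotations")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(rec$fs_lfp_hz, fid, "fs_lfp_hz")
  if (!is.null(rec$fs_mua_hz))
    rhdf5::h5writeAttribute(rec$fs_mua_hz, fid, "fs_mua_hz")
  rhdf5::h5writeAttribute(rec$spacing_um, fid, "spacing_um")
  rhdf5::h5writeAttribute(rec$signal_kind, fid, "signal_kind")
  rhdf5::h5writeAttribute(rec$zone, fid, "zone")
  rhdf5::h5writeAttribute(rec$line_freq_hz, fid, "line_freq_hz")
  rhdf5::h5writeAttribute(rec$channel_status, fid, "channel_status")
  rhdf5::h5writeAttribute("ictalcsd-1", fid, "container_version")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) rlang::abort("file not found.")
  at <- rhdf5::h5readAttributes(path, "/")
  required <- c("fs_lfp_hz", "spacing_um", "signal_kind", "zone",
                "line_freq_hz")
  missing <- setdiff(required, names(at))
  if (length(missing))
    rlang::abort(sprintf("container lacks required attribute(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "ictalcsd_schema_error")
  if (at$fs_lfp_hz <= 0)
    rlang::abort("fs_lfp_hz must be positive.",
                 class = "ictalcsd_schema_error")
  contents <- rhdf5::h5ls(path)$name
  lfp <- rhdf5::h5read(path, "lfp")
  mua <- if ("mua" %in% contents) rhdf5::h5read(path, "mua") else NULL
  ann <- if ("annotations" %in% contents) {
    a <- rhdf5::h5read(path, "annotations")
    a[] <- lapply(a, as.vector)   # drop HDF5 1-d array dims
    tibble::as_tibble(a)
  } else NULL
  laminar_recording(
    lfp = lfp, fs_lfp_hz = as.numeric(at$fs_lfp_hz), mua = mua,
    fs_mua_hz = if (!is.null(at$fs_mua_hz)) as.numeric(at$fs_mua_hz) else NULL,
    spacing_um = as.numeric(at$spacing_um),
    signal_kind = as.character(at$signal_kind),
    zone = as.character(at$zone),
    line_freq_hz = as.numeric(at$line_freq_hz),
    annotations = ann,
    channel_status = if (!is.null(at$channel_status))
      as.character(at$channel_status) else NULL)
}

#' Write / read an event table as CSV
#'
#' Times are seconds from recording start; values survive the roundtrip to
#' at least six decimals.
#'
#' @param events tibble of events (e.g. `discharge_set$events`).
#' @param path CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Export the LFP band to EDF
#'
#' Minimal EDF (16-bit) export of the LFP channels. Each channel is
#' quantized to its own physical range, so the export is lossy by
#' construction (documented); record duration is 1 s.
#'
#' @param rec a [laminar_recording()].
#' @param path output path (`.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$lfp
  ns <- nrow(x)
  fs <- round(rec$fs_lfp_hz)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) rlang::abort("recording shorter than one EDF record (1 s).")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  pad <- function(s, w)
    substr(formatC(as.character(s), width = w, flag = "-"), 1, w)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    pad("0", 8),                              # version
    pad("ictalcsd laminar export", 80),       # patient id
    pad("synthetic laminar recording", 80),   # recording id
    pad("01.01.00", 8), pad("00.00.00", 8),   # date, time
    pad(256 + ns * 256, 8),                   # header bytes
    pad("", 44),                              # reserved
    pad(n_rec, 8), pad("1", 8), pad(ns, 4))   # n records, duration, ns
  writeChar(hdr, con, eos = NULL)
  # round the physical range outward so it prints in 8 bytes exactly
  phys_min <- floor(apply(x, 1, min) * 100) / 100
  phys_max <- ceiling(apply(x, 1, max) * 100) / 100
  same <- phys_max - phys_min < 1e-9
  phys_max[same] <- phys_min[same] + 1
  fields <- list(
    label = sprintf("LFP%02d", seq_len(ns)),
    transducer = rep("", ns), dim = rep("uV", ns),
    pmin = sprintf("%.2f", phys_min),
    pmax = sprintf("%.2f", phys_max),
    dmin = rep("-32768", ns), dmax = rep("32767", ns),
    prefilter = rep("", ns), nsamp = rep(fs, ns), reserved = rep("", ns))
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  for (f in seq_along(fields))
    writeChar(paste0(vapply(fields[[f]], pad, character(1), widths[f]),
                     collapse = ""), con, eos = NULL)
  # digital conversion per channel
  scale <- (32767 - (-32768)) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((x[i, cols] - phys_min[i]) * scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Write an engagement matrix as CSV
#'
#' One row per contact/group, 100 columns (`bin_1` ... `bin_100`).
#'
#' @param em an `engagement_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_engagement <- function(em, path) {
  d <- as.data.frame(em$values)
  names(d) <- paste0("bin_", seq_len(ncol(d)))
  d <- cbind(row = em$rows, d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run-provenance sidecar
#'
#' Writes a JSON log of the configuration hash, seed and package version
#' next to a pipeline product.
#'
#' @param config any R object describing the run configuration.
#' @param seed the run seed.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, seed, path) {
  jsonlite::write_json(
    list(config_hash = rlang::hash(config), seed = seed,
         package = "ictalcsd",
         version = as.character(utils::packageVersion("ictalcsd")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Scalar fields of [simulation_config()] can be overridden from a config
#' file; nested lists (`noise`, `mua`) merge with the defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [simulation_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        names(formals(simulation_config)))]
  defaults <- formals(simulation_config)
  for (nested in c("noise", "mua")) {
    if (!is.null(raw[[nested]])) {
      base <- eval(defaults[[nested]])
      base[names(raw[[nested]])] <- raw[[nested]]
      args[[nested]] <- base
    }
  }
  do.call(simulation_config, args)
}
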