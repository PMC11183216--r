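#' Run the full laminar seizure analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> detect -> CSD -> MUA ->
#' layer stats -> engagement -> ICA patterns as one reproducible run. A
#' single global seed fans out to per-stage child seeds through stable
#' hashing of the stage name, so adding or removing a stage never perturbs
#' another stage's random stream. Stage dependencies are checked up front.
#'
#' @param config a [simulation_config()] (the recording is simulated) or
#'   `NULL` when `recording` is supplied.
#' @param recording optional [laminar_recording()] analysed instead of a
#'   simulation (detection scores then require `truth`).
#' @param truth optional ground-truth list (as produced by
#'   [simulate_seizure()]) for detection scoring.
#' @param seed global seed (defaults to `config$seed`).
#' @param stages character vector of stages to run, a subset of
#'   `c("detect", "mua", "stats", "engagement", "ica")`; CSD and
#'   preprocessing always run.
#' @param partition a [layer_partition()].
#' @param detector a [detector_params()].
#' @param out_dir optional directory: recording container, event CSV,
#'   engagement CSV and a provenance JSON are written there.
#' @return list of class `pipeline_report`: `detection` (events +
#'   `scores` when truth is known), `layer_stats`, `peak_counts`,
#'   `alternation`, `engagement` (+ `onsets` per group), `patterns`,
#'   `mua` (`depth_fraction`), `provenance`.
#' @export
run_pipeline <- function(config = NULL, recording = NULL, truth = NULL,
                         seed = NULL,
                         stages = c("detect", "mua", "stats", "engagement",
                                    "ica"),
                         partition = layer_partition(),
                         detector = detector_params(), out_dir = NULL) {
  if (is.null(config) && is.null(recording))
    rlang::abort("supply a simulation config or a recording.")
  bad <- setdiff(stages, c("detect", "mua", "stats", "engagement", "ica"))
  if (length(bad))
    rlang::abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  needs <- list(stats = "detect", ica = "detect")
  for (st in names(needs)) {
    if (st %in% stages && !all(needs[[st]] %in% stages))
      rlang::abort(sprintf("stage '%s' requires upstream stage '%s'.",
                           st, needs[[st]]),
                   class = "ictalcsd_dependency_error")
  }
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1L
  if (!is.null(config)) {
    sim <- simulate_seizure(config)
    recording <- sim$recording
    truth <- sim$truth
  }
  report <- list()
  rec <- filter_bands(recording)
  csd <- compute_csd(rec)
  csd_norm <- rescale_sinks_sources(csd, interval = "seizure")

  det <- NULL
  if ("detect" %in% stages) {
    det <- detect_discharges(rec, detector)
    report$detection <- list(events = det$events)
    if (!is.null(truth)) {
      report$detection$scores <- evaluate_detection(
        det, truth$events$time_s,
        duration_s = ncol(rec$lfp) / rec$fs_lfp_hz)
    }
  }
  if ("stats" %in% stages) {
    report$peak_counts <- peak_layer_counts(csd, det, partition)
    report$layer_stats <- sink_source_layer_stats(
      list(csd_norm), partition,
      zone = if (rec$zone == "propagation") "propagation" else "onset")
    report$alternation <- alternation_index(csd, det)
  }
  if ("engagement" %in% stages) {
    binned <- normalize_seizure_time(csd)
    base <- engagement_baseline(csd, binned$bin_dur_s)
    em <- engagement_matrix(binned, base, partition = partition)
    onsets <- purrr::map_dfr(seq_len(nrow(em$values)), function(r) {
      dplyr::mutate(engagement_onset(em$values[r, ]),
                    group = em$rows[r], .before = 1)
    })
    report$engagement <- list(matrix = em, onsets = onsets)
  }
  if ("ica" %in% stages) {
    win <- build_event_windows(csd, det)
    dec <- decompose_discharges(win, seed = derive_seed(seed, "ica"))
    report$patterns <- count_patterns(dec, win)
  }
  if ("mua" %in% stages && !is.null(rec$mua)) {
    mr <- estimate_mua_rate(rec)
    report$mua <- list(depth_fraction = depth_fraction(mr),
                       baseline = mr$baseline)
  }
  report$provenance <- list(
    config_hash = rlang::hash(list(config = config, seed = seed,
                                   stages = stages)),
    seed = seed, stages = stages)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_recording(recording, file.path(out_dir, "recording.h5"))
    if (!is.null(det)) write_events(det$events, file.path(out_dir, "events.csv"))
    if (!is.null(report$engagement))
      write_engagement(report$engagement$matrix,
                       file.path(out_dir, "engagement.csv"))
    write_provenance(list(config = config, stages = stages), seed,
                     file.path(out_dir, "provenance.json"))
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$detection)) {
    cat(sprintf("  detection: %d events", nrow(x$detection$events)))
    if (!is.null(x$detection$scores))
      cat(sprintf(" (sens %.2f, spec %.2f)", x$detection$scores$sensitivity,
                  x$detection$scores$specificity))
    cat("\n")
  }
  if (!is.null(x$patterns))
    cat(sprintf("  patterns: %d\n", x$patterns$n_patterns))
  if (!is.null(x$mua))
    cat(sprintf("  MUA deepest-fraction: %.2f\n", x$mua$depth_fraction))
  invisible(x)
}
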