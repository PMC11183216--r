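#' Laminar discharge motif
#'
#' A motif couples a zero-sum laminar CSD profile (sinks positive, sources
#' negative, arbitrary units) with a biphasic temporal kernel and a
#' per-contact multiplier for discharge-locked multi-unit firing. The spatial
#' polarity of the kernel's second lobe flips `alternation_lag_ms` after
#' discharge onset, reproducing the sink-to-source alternation seen at ictal
#' discharges.
#'
#' @param motif_id label.
#' @param csd_profile numeric vector, one weight per contact, `sum == 0`.
#' @param duration_ms total kernel duration (first lobe runs up to
#'   `alternation_lag_ms`, the flipped lobe fills the remainder).
#' @param amplitude kernel peak amplitude (arbitrary units; the simulator
#'   rescales against the realised noise floor).
#' @param alternation_lag_ms lag at which spatial polarity flips (ms).
#' @param second_lobe_gain amplitude of the flipped lobe relative to the
#'   first. Kept below the detector's amplitude threshold relative to the
#'   main lobe so each discharge yields a single detection.
#' @param mua_depth_profile non-negative per-contact spike-rate multipliers.
#'
#' @return object of class `laminar_motif`.
#' @export
laminar_motif <- function(motif_id, csd_profile, duration_ms = 80,
                          amplitude = 1, alternation_lag_ms = 50,
                          second_lobe_gain = 0.25,
                          mua_depth_profile = NULL) {
  if (abs(sum(csd_profile)) > 1e-8 * max(abs(csd_profile), 1))
    rlang::abort(
      "csd_profile must be zero-sum: injected sinks and sources must balance (current conservation).",
      class = "ictalcsd_conservation_error")
  if (duration_ms <= 0) rlang::abort("duration_ms must be > 0.")
  if (alternation_lag_ms <= 0 || alternation_lag_ms >= duration_ms)
    rlang::abort("alternation_lag_ms must lie inside the kernel duration.")
  if (is.null(mua_depth_profile))
    mua_depth_profile <- rep(0, length(csd_profile))
  if (length(mua_depth_profile) != length(csd_profile) ||
      any(mua_depth_profile < 0))
    rlang::abort("mua_depth_profile must be non-negative, one value per contact.")
  structure(
    list(motif_id = motif_id, csd_profile = as.numeric(csd_profile),
         duration_ms = duration_ms, amplitude = amplitude,
         alternation_lag_ms = alternation_lag_ms,
         second_lobe_gain = second_lobe_gain,
         mua_depth_profile = as.numeric(mua_depth_profile)),
    class = "laminar_motif")
}

#' Forward model: laminar LFP snapshot from a CSD profile
#'
#' Solves the discrete Poisson problem that is the exact inverse of the CSD
#' estimator: find per-contact potentials `phi` such that the second spatial
#' difference `(phi[i-1] - 2 phi[i] + phi[i+1]) / h^2`, with zero virtual
#' channels above and below the array, reproduces `csd_profile` exactly on
#' every contact. Potentials generated this way round-trip through
#' [compute_csd()] to machine precision.
#'
#' @param csd_profile zero-sum numeric vector, length >= 3 (sinks positive).
#' @param spacing_um contact spacing h in micrometres.
#' @return numeric vector of per-contact potentials (arbitrary units), with
#'   both virtual boundary potentials equal to 0.
#' @export
#' @examples
#' prof <- c(1, -2, 1, 0, 0, 0)
#' phi <- forward_lfp_from_csd(prof, 150)
#' # second difference with zero-padded boundaries recovers prof
forward_lfp_from_csd <- function(csd_profile, spacing_um = 150) {
  n <- length(csd_profile)
  if (n < 3) rlang::abort("csd_profile must have length >= 3.")
  if (abs(sum(csd_profile)) > 1e-8 * max(abs(csd_profile), 1))
    rlang::abort(
      "csd_profile must be zero-sum (current conservation violated).",
      class = "ictalcsd_conservation_error")
  h <- spacing_um / 1000  # work in mm so amplitudes stay O(1)
  A <- diag(-2, n)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- 1
  as.numeric(solve(A, h^2 * csd_profile))
}

# --- default motif tables ---------------------------------------------------

# Default layer boundaries for a 24-contact array (see layer_partition()).
# Onset-zone motifs live strictly below contact 11 so that 5-point Hamming
# smoothing cannot leak discharge energy into the supragranular group.

# Phase-1 onset motif: sinks in the granular/upper-infragranular cortex and
# in the deepest infragranular contacts, flanking a mid-infragranular source.
onset_phase1_profile <- function(n = 24) {
  p <- numeric(n)
  p[12:13] <- 0.6    # granular / border sink
  p[14:15] <- 0.9    # superficial infragranular sink
  p[17:21] <- NA     # source, filled to balance
  p[23:24] <- 0.9
  src <- -sum(p, na.rm = TRUE) / 5
  p[17:21] <- src
  p
}

# Phase-2 onset motif: broad sink over granular + superficial infragranular,
# source confined to the deepest contacts.
onset_phase2_profile <- function(n = 24) {
  p <- numeric(n)
  p[12:19] <- 1
  p[22:24] <- -sum(p) / 3
  p
}

# Propagation-zone base motif: superficial supragranular sink over a slightly
# deeper supragranular source.
propagation_base_profile <- function(n = 24) {
  p <- numeric(n)
  p[1:4] <- 1
  p[6:9] <- -1
  p
}

# Recruited granular component (switches on at the granular recruitment
# fraction of normalized seizure time). Balanced within the granular band
# (central sink, flanking sources) so recruitment does not bleed into the
# neighbouring groups.
propagation_granular_profile <- function(n = 24) {
  p <- numeric(n)
  p[12] <- 2
  p[c(11, 13)] <- -1
  p
}

# Recruited infragranular component.
propagation_infra_profile <- function(n = 24) {
  p <- numeric(n)
  p[17:20] <- 1
  p[22:24] <- -4 / 3
  p
}

# Discharge-locked MUA depth profiles: onset-zone firing dominated by the
# deepest infragranular contacts; propagation-zone firing by the most
# superficial supragranular contacts.
onset_mua_profile <- function(n = 24) {
  p <- numeric(n)
  p[11:13] <- 0.3
  p[14:19] <- 0.5
  p[20:24] <- 3
  p
}

propagation_mua_profile <- function(n = 24) {
  p <- numeric(n)
  p[1:5] <- 2
  p[6:10] <- 1
  p[11:13] <- 0.8
  p[14:18] <- 0.5
  p[19:24] <- 0.1
  p
}

#' Default motif set for a zone
#'
#' Motifs emulate the qualitative laminar organisation of ictal discharges:
#' onset-zone discharges involve only granular and infragranular contacts
#' (two successive motifs, one per seizure phase), propagation-zone
#' discharges carry a dominant supragranular dipole with weaker granular and
#' infragranular components that are recruited later in the seizure.
#'
#' @param zone `"onset"` or `"propagation"`.
#' @param n_contacts number of contacts (default 24).
#' @return named list of [laminar_motif()] objects.
#' @export
default_motifs <- function(zone, n_contacts = 24) {
  zone <- match.arg(zone, c("onset", "propagation"))
  n <- n_contacts
  if (zone == "onset") {
    list(
      deep_flank = laminar_motif("deep_flank", onset_phase1_profile(n),
                                 mua_depth_profile = onset_mua_profile(n)),
      deep_broad = laminar_motif("deep_broad", onset_phase2_profile(n),
                                 mua_depth_profile = onset_mua_profile(n)))
  } else {
    list(
      superficial = laminar_motif("superficial", propagation_base_profile(n),
                                  mua_depth_profile = propagation_mua_profile(n)),
      recruit_granular = laminar_motif(
        "recruit_granular", propagation_granular_profile(n),
        amplitude = 0.35,
        mua_depth_profile = numeric(n)),
      recruit_infra = laminar_motif(
        "recruit_infra", propagation_infra_profile(n),
        amplitude = 0.25,
        mua_depth_profile = numeric(n)))
  }
}
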