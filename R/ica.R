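#' Discharge-triggered CSD windows
#'
#' Extracts a `win_s` window of the CSD centred on each event peak and
#' normalizes each window by its own max |CSD| (per-window scale
#' normalization); events whose window would extend beyond the recording
#' are dropped (count reported).
#'
#' @param csd a `csd_matrix`.
#' @param events event times (s) or a `discharge_set`.
#' @param win_s window length (default 1.0).
#' @param taper `"gaussian"` (default), `"hann"` or `"none"`: temporal taper
#'   applied after scale normalization. Discharges repeat every ~140 ms at
#'   ictal rates, so an untapered 1-s window is dominated by the placement
#'   jitter of neighbouring discharges; a centre-emphasizing taper keeps the
#'   decomposition focused on the aligned central discharge.
#' @param taper_sd_s SD of the Gaussian taper in seconds (default 0.05).
#' @return object of class `event_windows`: `data` (events x (channels *
#'   samples) matrix), `n_channels`, `n_samples`, `event_times` of retained
#'   events, `n_dropped`.
#' @export
build_event_windows <- function(csd, events, win_s = 1.0,
                                taper = c("gaussian", "hann", "none"),
                                taper_sd_s = 0.05) {
  taper <- match.arg(taper)
  if (inherits(events, "discharge_set")) events <- events$events$time_s
  fs <- csd$fs_hz
  half <- round(win_s * fs / 2)
  n_w <- 2L * half
  n_samp <- ncol(csd$values)
  centers <- round(events * fs) + 1L
  ok <- (centers - half) >= 1 & (centers + half - 1) <= n_samp
  if (!any(ok))
    rlang::abort("no event window fits inside the recording.",
                 class = "ictalcsd_empty_error")
  centers_ok <- centers[ok]
  nch <- nrow(csd$values)
  tp <- switch(taper,
    gaussian = exp(-0.5 * ((seq_len(n_w) - half) / (taper_sd_s * fs))^2),
    hann = 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n_w))),
    none = rep(1, n_w))
  X <- matrix(0, length(centers_ok), nch * n_w)
  for (e in seq_along(centers_ok)) {
    w <- csd$values[, (centers_ok[e] - half):(centers_ok[e] + half - 1)]
    mx <- max(abs(w))
    if (mx > 0) w <- w / mx
    X[e, ] <- as.numeric(sweep(w, 2, tp, "*"))
  }
  structure(list(data = X, n_channels = nch, n_samples = n_w,
                 event_times = events[ok], n_dropped = sum(!ok),
                 channels = csd$channels, fs_hz = fs),
            class = "event_windows")
}

#' Fixed-point ICA decomposition of discharge windows
#'
#' Whitens the event x features matrix by PCA (retaining `n_components`
#' principal dimensions) and rotates with fixed-point (FastICA-type) ICA.
#' The second-moment decomposition is deliberately uncentered: ictal
#' discharges express one laminar motif at a time, so motif identity is a
#' sparse non-negative activation that appears as one ray from the origin
#' per motif; mean-centering would collapse mutually exclusive motifs onto
#' a single difference axis. Components are ordered by explained variance
#' (uncentered second moment), descending. Deterministic for a given seed.
#'
#' @param windows an `event_windows` object.
#' @param n_components number of components (default 8; reduced to the
#'   matrix rank with a warning when events are scarce).
#' @param seed integer seed for the ICA rotation initialisation.
#' @return object of class `ica_decomposition`: `loadings` (events x
#'   components source activations), `components` (components x features
#'   spatial-temporal patterns), `explained_var` (share of total variance
#'   per component), `event_times`, window geometry.
#' @export
decompose_discharges <- function(windows, n_components = 8, seed = 1L) {
  X <- windows$data
  n <- nrow(X)
  if (n < 2) rlang::abort("need at least two event windows.",
                          class = "ictalcsd_empty_error")
  # uncentered PCA via the n x n Gram matrix (features >> events)
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  rank <- sum(pos)
  nc <- n_components
  if (rank < nc) {
    rlang::warn(sprintf("rank %d < %d components: reducing.", rank, nc))
    nc <- rank
  }
  U <- eg$vectors[, seq_len(nc), drop = FALSE]
  d <- sqrt(eg$values[seq_len(nc)])
  # whitened scores: unit variance per retained dimension
  Z <- U * sqrt(n - 1)
  # feature-space principal axes (features x nc)
  V <- crossprod(X, sweep(U, 2, d, "/"))
  set.seed(seed)
  R0 <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
  ic <- ica::icafast(Z, nc = nc, center = FALSE, Rmat = R0)
  # source activations per event and patterns in feature space
  S <- ic$S                       # n x nc, unit variance sources
  M <- ic$M                       # nc x nc mixing (Z ~ S %*% t(M))
  patt <- t(sweep(M, 1, d / sqrt(n - 1), "*")) %*% t(V)  # nc x features
  # explained variance share: sources have unit variance, so each
  # component's variance contribution is its pattern's squared norm
  total_var <- sum(eg$values) / (n - 1)
  comp_var <- rowSums(patt^2)
  share <- comp_var / max(total_var, .Machine$double.eps)
  ord <- order(share, decreasing = TRUE)
  structure(list(loadings = S[, ord, drop = FALSE],
                 components = patt[ord, , drop = FALSE],
                 explained_var = share[ord],
                 event_times = windows$event_times,
                 n_channels = windows$n_channels,
                 n_samples = windows$n_samples,
                 channels = windows$channels,
                 n_components = nc, seed = seed),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components over %d events; var shares: %s\n",
              x$n_components, nrow(x$loadings),
              paste(sprintf("%.2f", x$explained_var), collapse = " ")))
  invisible(x)
}

#' Count temporally organized discharge patterns
#'
#' Components with an explained-variance share below `retain_var` are
#' discarded (the share is measured on the uncentered second moment, where
#' the dominant motif's component carries most of the mass); each event is assigned to its dominant retained component
#' (largest |loading|); components whose mean assigned-window correlation
#' reaches `merge_corr` are merged (single-linkage); a merged group is a
#' pattern when it covers at least `min_support` of all events and is
#' temporally contiguous: within its decile-trimmed time interval
#' (10th-90th percentile of its event times) at least `contiguity` of all
#' events belong to the group. Epochs are ordered by median event time and
#' the switch time between adjacent patterns is the midpoint of the optimal
#' 1-D separation boundary between their event times.
#'
#' @param decomp an `ica_decomposition`.
#' @param windows the `event_windows` the decomposition came from (used for
#'   merge correlations and mean motifs).
#' @param retain_var minimum explained-variance share (default 0.01).
#' @param merge_corr centroid correlation at or above which components merge
#'   (default 0.9).
#' @param min_support minimum fraction of all events per pattern
#'   (default 0.02).
#' @param contiguity minimum within-epoch purity (default 0.8).
#' @return object of class `pattern_result`: `n_patterns` (contiguous
#'   patterns), `patterns` (list with `motif` channels x samples mean
#'   window, `component_ids`, `epoch_s`, `n_events`, `contiguous`),
#'   `candidates` (all supported groups, including non-contiguous ones,
#'   flagged), `assignment` tibble (`event_time_s`, `component`,
#'   `pattern`), `switch_times_s`.
#' @export
count_patterns <- function(decomp, windows, retain_var = 0.01,
                           merge_corr = 0.9, min_support = 0.02,
                           contiguity = 0.8) {
  keep <- which(decomp$explained_var >= retain_var)
  n_ev <- nrow(decomp$loadings)
  times <- decomp$event_times
  if (!length(keep)) {
    rlang::warn("no component reaches the retention threshold.")
    return(structure(list(n_patterns = 0L, patterns = list(),
                          assignment = tibble::tibble(
                            event_time_s = times,
                            component = NA_integer_, pattern = NA_integer_),
                          switch_times_s = numeric(0)),
                     class = "pattern_result"))
  }
  # weight whitened loadings by each component's energy scale so that the
  # assignment reflects actual window-energy contributions, not whitened
  # (variance-equalized) units
  L <- sweep(abs(decomp$loadings[, keep, drop = FALSE]), 2,
             sqrt(decomp$explained_var[keep]), "*")
  comp_of <- keep[max.col(L, ties.method = "first")]
  # centroid (mean assigned window) per active component
  active <- sort(unique(comp_of))
  centroids <- t(vapply(active, function(k)
    colMeans(windows$data[comp_of == k, , drop = FALSE]),
    numeric(ncol(windows$data))))
  # single-linkage merge on centroid correlation
  g <- seq_along(active)
  if (length(active) > 1) {
    cm <- stats::cor(t(centroids))
    repeat {
      done <- TRUE
      for (a in seq_along(active)) for (b in seq_along(active)) {
        if (g[a] != g[b] && cm[a, b] >= merge_corr) {
          g[g == g[b]] <- g[a]; done <- FALSE
        }
      }
      if (done) break
    }
  }
  merged_ids <- unique(g)
  groups <- lapply(merged_ids, function(m) active[g == m])
  ev_group <- match(g[match(comp_of, active)], merged_ids)
  # candidate patterns: support + contiguity
  pat <- list()
  for (m in seq_along(groups)) {
    sel <- ev_group == m
    support <- mean(sel)
    if (support < min_support) next
    tsel <- times[sel]
    q <- stats::quantile(tsel, c(0.1, 0.9), names = FALSE, type = 1)
    inside <- times >= q[1] & times <= q[2]
    purity <- if (any(inside)) sum(sel & inside) / sum(inside) else 0
    pat[[length(pat) + 1]] <- list(
      group = m, component_ids = groups[[m]],
      motif = matrix(colMeans(windows$data[sel, , drop = FALSE]),
                     windows$n_channels, windows$n_samples),
      n_events = sum(sel), support = support,
      median_time = stats::median(tsel),
      epoch_s = range(tsel), trimmed_epoch_s = q,
      contiguous = purity >= contiguity, purity = purity)
  }
  candidates <- pat
  if (length(pat)) {
    pat <- pat[order(vapply(pat, `[[`, numeric(1), "median_time"))]
    noncontig <- !vapply(pat, `[[`, logical(1), "contiguous")
    if (any(noncontig))
      rlang::warn(sprintf(
        "%d candidate pattern(s) fail the temporal-contiguity rule (interleaved events); reported as candidates only.",
        sum(noncontig)))
    candidates <- pat
    pat <- pat[!noncontig]
  }
  # switch times between adjacent patterns: optimal 1-D separation boundary
  switch_times <- numeric(0)
  if (length(pat) >= 2) {
    for (k in seq_len(length(pat) - 1)) {
      ta <- times[ev_group == pat[[k]]$group]
      tb <- times[ev_group == pat[[k + 1]]$group]
      cand <- sort(unique(c(ta, tb)))
      miscls <- vapply(cand, function(s) sum(ta > s) + sum(tb <= s),
                       numeric(1))
      s_opt <- cand[which.min(miscls)]
      after <- c(ta[ta > s_opt], tb[tb > s_opt])
      switch_times <- c(switch_times,
                        (s_opt + if (length(after)) min(after) else s_opt) / 2)
    }
  }
  assignment <- tibble::tibble(
    event_time_s = times, component = comp_of,
    pattern = vapply(ev_group, function(m) {
      p <- which(vapply(pat, function(pp) pp$group == m, logical(1)))
      if (length(p)) p else NA_integer_
    }, integer(1)))
  structure(list(n_patterns = length(pat), patterns = pat,
                 candidates = candidates,
                 assignment = assignment, switch_times_s = switch_times),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("<pattern_result> %d pattern(s)\n", x$n_patterns))
  for (k in seq_along(x$patterns)) {
    p <- x$patterns[[k]]
    cat(sprintf("  %d: %d events, epoch [%.1f, %.1f] s, contiguous: %s\n",
                k, p$n_events, p$epoch_s[1], p$epoch_s[2], p$contiguous))
  }
  if (length(x$switch_times_s))
    cat("  switch times (s):",
        paste(sprintf("%.2f", x$switch_times_s), collapse = ", "), "\n")
  invisible(x)
}
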