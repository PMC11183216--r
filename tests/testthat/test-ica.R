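mk_csd_i <- function(v, fs = 1000) {
  structure(list(values = v, spacing_um = 150, fs_hz = fs,
                 smoothing = "none", normalized = "raw",
                 channels = seq_len(nrow(v)), annotations = NULL),
            class = "csd_matrix")
}

# Event windows built directly from two orthogonal laminar motifs, with the
# small temporal jitter and additive noise real peak-aligned discharges
# carry (a few samples of alignment error at 2 kHz).
motif_windows <- function(n_a, n_b, noise = 0.05, seed = 1, max_shift = 3) {
  set.seed(seed)
  nch <- 8; nw <- 100
  base <- sin(2 * pi * seq_len(nw) / nw)
  n <- n_a + n_b
  X <- matrix(0, n, nch * nw)
  lab <- c(rep(1, n_a), rep(2, n_b))
  for (e in seq_len(n)) {
    sh <- sample(-max_shift:max_shift, 1) %% nw
    k <- c(utils::tail(base, sh), utils::head(base, nw - sh))
    pa <- if (lab[e] == 1) c(1, -1, rep(0, 6)) else c(rep(0, 6), 1, -1)
    w <- outer(pa, k) + rnorm(nch * nw, sd = noise)
    X[e, ] <- as.numeric(w / max(abs(w)))
  }
  structure(list(data = X, n_channels = nch, n_samples = nw,
                 event_times = seq_len(n) * 0.2, n_dropped = 0L,
                 channels = 1:8, fs_hz = 1000),
            class = "event_windows")
}

test_that("events too close to the recording edge are dropped", {
  v <- matrix(rnorm(4 * 60000), 4)
  w <- build_event_windows(mk_csd_i(v), c(0.3, 30, 45), win_s = 1)
  expect_equal(w$n_dropped, 1L)
  expect_equal(nrow(w$data), 2L)
  expect_equal(w$event_times, c(30, 45))
  expect_error(build_event_windows(mk_csd_i(v), 0.1),
               class = "ictalcsd_empty_error")
})

test_that("windows of an identical repeated discharge correlate above 0.95", {
  v <- matrix(0, 6, 60000)
  kern <- sin(2 * pi * seq_len(100) / 100)
  ev <- c(10, 20, 30, 40)
  for (tt in ev) v[3, round(tt * 1000) + seq_along(kern)] <- kern
  v <- v + matrix(rnorm(length(v), sd = 0.02), nrow(v))
  w <- build_event_windows(mk_csd_i(v), ev + 0.05)
  cc <- cor(t(w$data))
  expect_true(all(cc[upper.tri(cc)] > 0.95))
})

test_that("two orthogonal motifs are captured by the top two components", {
  w <- motif_windows(40, 40)
  dec <- decompose_discharges(w, n_components = 8, seed = 1)
  expect_gt(sum(dec$explained_var[1:2]), 0.9)
  # PCA variance oracle on the same matrix
  sv <- svd(w$data, nu = 0, nv = 0)$d^2
  expect_gt(sum(sv[1:2]) / sum(sv), 0.9)
})

test_that("decomposition is deterministic for a fixed seed", {
  w <- motif_windows(30, 30)
  d1 <- decompose_discharges(w, seed = 7)
  d2 <- decompose_discharges(w, seed = 7)
  expect_identical(d1$loadings, d2$loadings)
})

test_that("fewer events than components reduces the order with a warning", {
  w <- motif_windows(3, 2)
  expect_warning(dec <- decompose_discharges(w, n_components = 8),
                 "reducing")
  expect_lte(dec$n_components, 5)
  expect_error(
    decompose_discharges(motif_windows(1, 0)),
    class = "ictalcsd_empty_error")
})

test_that("a single-motif event set yields one pattern", {
  w <- motif_windows(60, 0)
  dec <- decompose_discharges(w, seed = 2)
  pr <- suppressWarnings(count_patterns(dec, w))
  expect_equal(pr$n_patterns, 1L)
  expect_equal(length(pr$switch_times_s), 0)
})

test_that("two disjoint-epoch motifs yield two patterns and a switch time", {
  w <- motif_windows(50, 150)    # epochs: events 1-50 then 51-200
  dec <- decompose_discharges(w, seed = 3)
  pr <- count_patterns(dec, w)
  expect_equal(pr$n_patterns, 2L)
  expect_true(all(vapply(pr$patterns, `[[`, logical(1), "contiguous")))
  # boundary between event 50 (t = 10.0) and 51 (t = 10.2)
  expect_lt(abs(pr$switch_times_s - 10.1), 0.2)
  # epochs ordered by median time and every assigned event in one pattern
  expect_true(all(table(pr$assignment$pattern) > 0))
})

test_that("alternating motifs are flagged as non-contiguous", {
  w <- motif_windows(100, 50)
  # interleave A,A,B,A,A,B,... in time: both motifs present throughout
  idx <- integer(0); ia <- 1; ib <- 101
  for (k in 1:50) { idx <- c(idx, ia, ia + 1, ib); ia <- ia + 2; ib <- ib + 1 }
  w$data <- w$data[idx, ]
  dec <- decompose_discharges(w, seed = 4)
  expect_warning(pr <- count_patterns(dec, w), "contiguity")
  expect_true(any(!vapply(pr$candidates, `[[`, logical(1), "contiguous")))
  expect_lt(pr$n_patterns, 2)    # interleaved groups are not epochs
})

test_that("pattern count is invariant to event-order shuffling", {
  w <- motif_windows(50, 150)
  set.seed(99)
  perm <- sample(200)
  ws <- w
  ws$data <- w$data[perm, ]
  ws$event_times <- w$event_times[perm]
  pr1 <- count_patterns(decompose_discharges(w, seed = 5), w)
  pr2 <- count_patterns(decompose_discharges(ws, seed = 5), ws)
  expect_equal(pr2$n_patterns, pr1$n_patterns)
  expect_equal(pr2$switch_times_s, pr1$switch_times_s, tolerance = 0.3)
})
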