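# Internal helpers shared across modules.

# 1/f ("pink") noise of length n, unit variance, via spectral shaping of
# white Gaussian noise. Amplitude at DC is zeroed so traces are mean-free.
pink_noise <- function(n) {
  stopifnot(n >= 2)
  nfft <- 2L * n
  white <- stats::rnorm(nfft)
  spec <- stats::fft(white)
  f <- c(1, seq_len(nfft - 1))      # avoid division by zero at DC
  f <- pmin(f, nfft - f + 1)        # mirror for negative frequencies
  spec <- spec / sqrt(f)
  spec[1] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# Robust SD via MAD with the Gaussian consistency constant.
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

# Derive a reproducible child seed from a parent seed and a stage label.
# Stable under adding stages: depends only on (seed, label).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Welch two-sample t test that tolerates zero-variance segments.
# Returns list(statistic, p.value, mean_early, mean_late).
welch_t <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 == 0) {
    # degenerate: both segments constant
    p <- if (my != mx) 0 else 1
    return(list(statistic = if (my != mx) Inf else 0, p.value = p,
                mean_early = mx, mean_late = my))
  }
  tt <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / max(length(x) - 1, 1) +
                 (vy / length(y))^2 / max(length(y) - 1, 1))
  if (!is.finite(df) || df <= 0) df <- 1
  p <- 2 * stats::pt(-abs(tt), df)
  list(statistic = tt, p.value = p, mean_early = mx, mean_late = my)
}

# Clamp helper.
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' @importFrom stats pt
NULL
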