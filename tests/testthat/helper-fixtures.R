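# Shared fixtures and independent oracles used across the suite.

# Small pilot-schedule simulation (4 sessions x few replicates) for
# pipeline-level tests.
small_pilot <- function(reps = 5, seed = 7, noise_sd = NULL, jitter_sd = NULL) {
  cfg <- default_config("pilot", seed = seed)
  cfg$spectra_per_session <- as.integer(reps)
  if (!is.null(noise_sd)) cfg$noise_sd <- noise_sd
  if (!is.null(jitter_sd)) cfg$replicate_jitter_sd <- jitter_sd
  cfg
}

# True background of a simulation config on a given axis (mirrors the
# generator's documented model: polynomial in scaled coordinate plus
# exponential decay).
true_background <- function(cfg, x) {
  u <- (x - cfg$axis_min) / (cfg$axis_max - cfg$axis_min)
  b <- numeric(length(x))
  for (k in seq_along(cfg$baseline_coeffs))
    b <- b + cfg$baseline_coeffs[k] * u^(k - 1)
  if (!is.null(cfg$baseline_decay) && cfg$baseline_exp_amp != 0)
    b <- b + cfg$baseline_exp_amp * exp(-cfg$baseline_decay * (x - cfg$axis_min))
  b
}

# Brute-force O(n^2)-chord greatest convex minorant: at each point the
# minimum over all data-point chords spanning it. Independent of the
# monotone-chain hull used by the implementation.
brute_force_lower_hull <- function(x, y) {
  n <- length(x)
  bf <- rep(Inf, n)
  for (j in seq_len(n)) {
    bf[j] <- min(bf[j], y[j])
    for (k in seq_len(n)[-seq_len(j)]) {
      lam <- (x[j:k] - x[j]) / (x[k] - x[j])
      bf[j:k] <- pmin(bf[j:k], y[j] + lam * (y[k] - y[j]))
    }
  }
  bf
}

# Per-point least-squares polynomial fit (stats::lm), the brute-force
# Savitzky-Golay oracle including truncated one-sided edge windows.
sg_lm_oracle <- function(y, window, order) {
  n <- length(y)
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    d <- data.frame(o = (lo:hi) - i, y = y[lo:hi])
    unname(stats::predict(stats::lm(y ~ stats::poly(o, order, raw = TRUE), d),
                          data.frame(o = 0)))
  }, 0)
}

# Pooled two-group standard deviation.
pooled_sd <- function(a, b) {
  sqrt((stats::var(a) * (length(a) - 1) + stats::var(b) * (length(b) - 1)) /
         (length(a) + length(b) - 2))
}

expect_spectrum_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$axis, b$axis, tolerance = tol)
  expect_equal(a$intensities, b$intensities, tolerance = tol)
}
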