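test_that("cropping keeps inclusive endpoints and records the gap", {
  s <- new_spectrum(c(340, 350, 360), c(1, 2, 3))
  cs <- crop(s, list(c(350, 1800)))
  expect_equal(cs$axis, c(350, 360))
  expect_equal(cs$intensities, c(2, 3))

  full <- new_spectrum(seq(300, 3100, 2), rep(1, 1401))
  cf <- crop(full)  # default ranges
  expect_true(all(cf$axis <= 1800 | cf$axis >= 2800))
  expect_true(any(cf$axis == 350) && any(cf$axis == 1800) &&
                any(cf$axis == 2800) && any(cf$axis == 3050))
  expect_false(any(cf$axis > 1800 & cf$axis < 2800))
  expect_equal(length(ramalgae:::axis_segments(cf$axis)), 2)

  ident <- crop(s, list(c(0, 5000)))
  expect_equal(ident$axis, s$axis)
  expect_error(crop(s, list(c(5000, 6000))), "ranges")
})

test_that("crop applies to whole sets and preserves metadata", {
  set <- simulate_spectra(small_pilot(reps = 1))
  cs <- crop(set)
  expect_s3_class(cs, "spectra_set")
  expect_identical(cs$meta, set$meta)
  expect_equal(ncol(cs$matrix), length(cs$axis))
})

test_that("rubberband reduces exactly to the convex hull oracle at bend -> 0", {
  set.seed(2)
  for (rep in 1:3) {
    x <- seq(0, 10, length.out = 200)
    y <- sin(x + rep) + 0.2 * x + stats::rnorm(200, 0, 0.1)
    rb <- concave_rubberband(new_spectrum(x, y), bend_angle = 1e-9, n_iter = 1)
    expect_equal(rb$baseline$intensities, brute_force_lower_hull(x, y),
                 tolerance = 1e-9)
  }
})

test_that("lines and constants are their own baseline", {
  x <- seq(350, 1800, 2)
  lin <- concave_rubberband(new_spectrum(x, 3 + 0.01 * x))
  expect_equal(max(abs(lin$corrected$intensities)), 0, tolerance = 1e-9)
  expect_equal(lin$baseline$intensities, 3 + 0.01 * x, tolerance = 1e-9)

  const <- concave_rubberband(new_spectrum(x, rep(5, length(x))))
  expect_equal(max(abs(const$corrected$intensities)), 0, tolerance = 1e-12)
})

test_that("corrected + baseline reconstructs the input exactly and stays non-negative", {
  cfg <- small_pilot(reps = 1)
  set <- crop(simulate_spectra(cfg))
  eps <- 1e-9 * diff(range(set$matrix))
  for (i in seq_len(min(10, n_spectra(set)))) {
    s <- get_spectrum(set, i)
    rb <- concave_rubberband(s)
    expect_identical(rb$corrected$intensities + rb$baseline$intensities,
                     s$intensities)
    expect_gte(min(rb$corrected$intensities), -eps)
  }
})

test_that("rubberband recovers a known quadratic background under a peak", {
  # single unit-amplitude peak on a quadratic background: recovered baseline
  # within 5% RMS of the peak amplitude
  x <- seq(350, 1800, 2)
  u <- (x - 350) / (1800 - 350)
  bg <- 4 + 3 * u - 2 * u^2
  peak <- exp(-(x - 1000)^2 / (2 * 15^2))
  rb <- concave_rubberband(new_spectrum(x, bg + peak))
  expect_lt(sqrt(mean((rb$baseline$intensities - bg)^2)), 0.05)
})

test_that("rubberband is nearly idempotent", {
  cfg <- small_pilot(reps = 1)
  s <- get_spectrum(crop(simulate_spectra(cfg)), 1)
  rb1 <- concave_rubberband(s)
  rb2 <- concave_rubberband(rb1$corrected)
  area1 <- sum(abs(rb1$corrected$intensities))
  removed <- sum(abs(rb2$baseline$intensities))
  expect_lt(removed, 0.01 * area1)
})

test_that("rubberband rejects degenerate segments", {
  expect_error(concave_rubberband(new_spectrum(c(1, 2), c(1, 2))), "3 points")
})

test_that("Savitzky-Golay reproduces polynomials up to the fit order", {
  x <- seq(350, 1800, 2)
  y <- 2 + 0.003 * x - 1e-6 * x^2
  sm <- savitzky_golay(new_spectrum(x, y), 25, 2, 1)
  expect_equal(sm$intensities, y, tolerance = 1e-9)
  # two passes as well, and edges (truncated windows) too
  sm2 <- savitzky_golay(new_spectrum(x, y), 25, 2, 2)
  expect_equal(sm2$intensities, y, tolerance = 1e-9)
})

test_that("Savitzky-Golay equals the per-point least-squares oracle", {
  # unit impulse isolates the filter's kernel rows, including the edge rows
  n <- 101
  for (pos in c(1, 7, 51, 101)) {
    y <- numeric(n); y[pos] <- 1
    sm <- savitzky_golay(new_spectrum(seq_len(n) * 2 + 300, y), 25, 2, 1)
    expect_equal(sm$intensities, sg_lm_oracle(y, 25, 2), tolerance = 1e-9)
  }
  # and a generic rough signal
  set.seed(4)
  y <- stats::rnorm(n)
  sm <- savitzky_golay(new_spectrum(seq_len(n) * 2 + 300, y), 11, 3, 1)
  expect_equal(sm$intensities, sg_lm_oracle(y, 11, 3), tolerance = 1e-9)
})

test_that("smoothing reduces white-noise variance", {
  set.seed(9)
  n <- 301
  vr <- replicate(200, {
    y <- stats::rnorm(n)
    sm <- savitzky_golay(new_spectrum(seq_len(n) + 300, y), 25, 2, 2)
    stats::var(sm$intensities) < stats::var(y)
  })
  expect_true(all(vr))
})

test_that("Savitzky-Golay input contracts are enforced", {
  s <- new_spectrum(1:10 + 300, stats::rnorm(10))
  expect_error(savitzky_golay(s, 4, 2), "odd")
  expect_error(savitzky_golay(s, 3, 3), "order")
  expect_error(savitzky_golay(s, 25, 2), "shorter")
})

test_that("SNV standardises and is affine-invariant", {
  s <- new_spectrum(c(400, 500, 600), c(1, 2, 3))
  expect_equal(snv(s)$intensities, c(-1, 0, 1))
  expect_error(snv(new_spectrum(c(1, 2, 3), c(5, 5, 5))), "constant")

  set.seed(3)
  y <- stats::rnorm(200)
  x <- seq(350, 748, 2)
  base <- snv(new_spectrum(x, y))$intensities
  scaled <- snv(new_spectrum(x, 2.7 * y + 13))$intensities
  expect_equal(scaled, base, tolerance = 1e-9)
  expect_equal(mean(base), 0, tolerance = 1e-12)
  expect_equal(stats::sd(base), 1, tolerance = 1e-12)
})

test_that("the full chain normalizes every spectrum and preserves metadata", {
  set <- simulate_spectra(small_pilot(reps = 2))
  prep <- preprocess(set)
  expect_identical(prep$meta, set$meta)
  expect_equal(max(abs(rowMeans(prep$matrix))), 0, tolerance = 1e-12)
  expect_equal(max(abs(apply(prep$matrix, 1, stats::sd) - 1)), 0,
               tolerance = 1e-12)
  lg <- attr(prep, "log")
  expect_equal(lg$points_in, 1401)
  expect_equal(lg$segments, 2)
})

test_that("the chain is invariant to a positive scale factor", {
  cfg <- small_pilot(reps = 1, noise_sd = 0, jitter_sd = 0)
  set <- simulate_spectra(cfg)
  a <- get_spectrum(set, 1)
  two <- new_spectra_set(a$axis, rbind(a$intensities, 3.5 * a$intensities),
                         data.frame(spectrum_id = c("a", "b"), day = 0,
                                    session = 0, replicate = 0:1))
  prep <- preprocess(two)
  expect_equal(prep$matrix[1, ], prep$matrix[2, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("zero-noise days stay identical through the chain", {
  cfg <- small_pilot(reps = 3, noise_sd = 0, jitter_sd = 0)
  prep <- preprocess(simulate_spectra(cfg))
  rows <- prep$matrix[prep$meta$day == 5, ]
  expect_equal(max(apply(rows, 2, stats::sd)), 0, tolerance = 1e-12)
})

test_that("stage errors name the offending spectrum", {
  x <- seq(350, 1800, 2)
  set.seed(12)
  good <- 5 + exp(-(x - 1000)^2 / 800) + 0.01 * stats::rnorm(length(x))
  bad <- new_spectra_set(x, rbind(good, rep(2, length(x))),
                         data.frame(spectrum_id = c("ok", "flatliner"),
                                    day = 0, session = 0, replicate = 0:1))
  expect_error(preprocess(bad), "flatliner")
})

test_that("preprocess_params validates its fields", {
  expect_error(preprocess_params(ranges = list()), "non-empty")
  expect_error(preprocess_params(ranges = list(c(2, 1))), "lo < hi")
  expect_error(preprocess_params(ranges = list(c(1, 5), c(4, 8))), "overlap")
  expect_error(preprocess_params(bend_angle = 95), "bend_angle")
  expect_error(preprocess_params(sg_window = 24), "odd")
  expect_error(preprocess_params(sg_passes = 0), "sg_passes")
})
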