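#' Pre-processing parameters
#'
#' Defaults follow common practice for fluorescence-dominated microalgal
#' Raman spectra: keep the fingerprint (350-1800 cm^-1) and C-H stretch
#' (2800-3050 cm^-1) windows, remove the background with ten iterations of
#' the concave (bent) rubberband at a 64 degree bending angle, smooth twice
#' with a 25-point quadratic Savitzky-Golay filter, then normalize each
#' spectrum by the standard normal variate.
#'
#' @param ranges List of inclusive `c(lo, hi)` wavenumber intervals (cm^-1).
#' @param bend_angle Concave bending angle in degrees, in (0, 90).
#' @param n_baseline_iter Rubberband iterations (>= 1).
#' @param sg_window Savitzky-Golay window length in points (odd, > sg_order).
#' @param sg_order Savitzky-Golay polynomial degree.
#' @param sg_passes Number of sequential smoothing passes (>= 1).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(ranges = list(c(350, 1800), c(2800, 3050)),
                              bend_angle = 64, n_baseline_iter = 10,
                              sg_window = 25, sg_order = 2, sg_passes = 2) {
  if (!length(ranges)) stop("ranges must be non-empty", call. = FALSE)
  for (r in ranges)
    if (length(r) != 2 || r[1] >= r[2])
      stop("each range must be c(lo, hi) with lo < hi", call. = FALSE)
  los <- vapply(ranges, `[`, 0, 1)
  his <- vapply(ranges, `[`, 0, 2)
  o <- order(los)
  if (length(ranges) > 1 && any(his[o][-length(o)] >= los[o][-1]))
    stop("ranges must not overlap", call. = FALSE)
  if (bend_angle <= 0 || bend_angle >= 90)
    stop("bend_angle must lie in (0, 90) degrees", call. = FALSE)
  if (n_baseline_iter < 1) stop("n_baseline_iter must be >= 1", call. = FALSE)
  if (sg_window %% 2 != 1 || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order", call. = FALSE)
  if (sg_passes < 1) stop("sg_passes must be >= 1", call. = FALSE)
  structure(list(ranges = lapply(ranges[o], as.numeric), bend_angle = bend_angle,
                 n_baseline_iter = as.integer(n_baseline_iter),
                 sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
                 sg_passes = as.integer(sg_passes)),
            class = "preprocess_params")
}

crop_mask <- function(axis, ranges) {
  keep <- rep(FALSE, length(axis))
  for (r in ranges) keep <- keep | (axis >= r[1] & axis <= r[2])
  keep
}

#' Crop a spectrum or spectra set to wavenumber ranges
#'
#' Retains exactly the axis points falling inside any interval (endpoints
#' inclusive). Disjoint segments stay concatenated in one vector; the axis
#' records the gap, and downstream stages (baseline, smoothing) treat each
#' contiguous segment independently.
#'
#' @param s A `spectrum` or `spectra_set`.
#' @param ranges List of inclusive `c(lo, hi)` intervals (cm^-1).
#' @return Object of the same class, cropped.
#' @export
crop <- function(s, ranges = list(c(350, 1800), c(2800, 3050))) {
  keep <- crop_mask(s$axis, ranges)
  if (!any(keep))
    stop("cropping removed every axis point; ranges were ",
         paste(vapply(ranges, function(r) sprintf("[%g, %g]", r[1], r[2]), ""),
               collapse = ", "), call. = FALSE)
  if (inherits(s, "spectrum")) {
    new_spectrum(s$axis[keep], s$intensities[keep], s$meta$spectrum_id,
                 s$meta$day, s$meta$session, s$meta$replicate)
  } else if (inherits(s, "spectra_set")) {
    new_spectra_set(s$axis[keep], s$matrix[, keep, drop = FALSE], s$meta)
  } else stop("crop expects a spectrum or spectra_set", call. = FALSE)
}

# Indices of the lower convex hull of (x, y), x strictly increasing
# (Andrew monotone chain; collinear interior points are dropped).
lower_hull_idx <- function(x, y) {
  n <- length(x)
  idx <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      i1 <- idx[m - 1L]; i2 <- idx[m]
      cr <- (x[i2] - x[i1]) * (y[i] - y[i1]) - (y[i2] - y[i1]) * (x[i] - x[i1])
      if (cr <= 0) m <- m - 1L else break
    }
    m <- m + 1L
    idx[m] <- i
  }
  idx[seq_len(m)]
}

rubberband_segment <- function(x, y, bend_angle, n_iter) {
  if (length(x) < 3)
    stop("concave rubberband needs at least 3 points per segment", call. = FALSE)
  x0 <- x[1]; x1 <- x[length(x)]
  dome <- (x - x0) * (x1 - x) / ((x1 - x0) / 2)^2  # in [0, 1], 0 at segment ends
  tb <- tan(bend_angle * pi / 180)
  w <- y
  baseline <- numeric(length(y))
  for (k in seq_len(n_iter)) {
    a <- diff(range(w))
    # hull in the bent frame: the concave bending term raises the hull so
    # broad concave backgrounds become touchable; at bend -> 0 (or for a
    # flat residual, where a = 0) this is the classic rubberband
    idx <- lower_hull_idx(x, w - tb * a * dome)
    est <- stats::approx(x[idx], w[idx], xout = x)$y
    w <- w - est
    baseline <- baseline + est
  }
  baseline
}

#' Concave (bent) rubberband baseline correction
#'
#' Iterative lower-convex-hull baseline estimation with concave bending,
#' applied independently to each contiguous axis segment (the cropped
#' fingerprint and C-H regions). Per iteration the hull of the working
#' spectrum is computed in a frame bent by
#' `tan(bend_angle) * A * (x - x0) * (x1 - x) / ((x1 - x0) / 2)^2`
#' (A the working intensity range, x0/x1 the segment ends); the baseline
#' estimate interpolates the working spectrum linearly between the hull touch
#' points and is subtracted before the next iteration. Bending lets the hull
#' follow broad concave fluorescence backgrounds a plain rubberband would cut
#' across. The corrected spectrum is non-negative up to interpolation
#' round-off, and `corrected + baseline` reconstructs the input.
#'
#' @param s A `spectrum` (typically already cropped).
#' @param bend_angle Bending angle in degrees, in (0, 90).
#' @param n_iter Number of hull iterations (>= 1).
#' @return List with `corrected` and `baseline`, both `spectrum` objects.
#' @export
concave_rubberband <- function(s, bend_angle = 64, n_iter = 10) {
  stopifnot(inherits(s, "spectrum"))
  segs <- axis_segments(s$axis)
  baseline <- numeric(length(s$axis))
  for (ix in segs)
    baseline[ix] <- rubberband_segment(s$axis[ix], s$intensities[ix],
                                       bend_angle, n_iter)
  corrected <- s$intensities - baseline
  baseline <- s$intensities - corrected  # bitwise: corrected + baseline == input
  m <- s$meta
  list(corrected = new_spectrum(s$axis, corrected, m$spectrum_id, m$day,
                                m$session, m$replicate),
       baseline = new_spectrum(s$axis, baseline,
                               paste0(m$spectrum_id, "_baseline"), m$day,
                               m$session, m$replicate))
}

# Value at `at` (offset units) of the LS polynomial of degree `order`
# fitted over integer offsets `offs`.
sg_fit_row <- function(offs, order, at = 0) {
  X <- outer(offs, 0:order, `^`)
  xa <- at^(0:order)
  drop(xa %*% solve(crossprod(X), t(X)))
}

sg_segment <- function(y, window, order, passes) {
  n <- length(y)
  if (n < window)
    stop(sprintf("segment of %d points is shorter than the %d-point smoothing window",
                 n, window), call. = FALSE)
  h <- (window - 1L) %/% 2L
  kern <- sg_fit_row(-h:h, order)       # symmetric central row
  # truncated one-sided rows for the h points at each edge
  left <- lapply(seq_len(h), function(i) sg_fit_row(seq_len(i + h) - i, order))
  for (p in seq_len(passes)) {
    smooth <- as.numeric(stats::filter(y, kern, method = "convolution", sides = 2))
    for (i in seq_len(h)) {
      smooth[i] <- sum(left[[i]] * y[seq_len(i + h)])
      j <- n - i + 1L
      smooth[j] <- sum(rev(left[[i]]) * y[seq.int(n - i - h + 1L, n)])
    }
    y <- smooth
  }
  y
}

#' Savitzky-Golay smoothing
#'
#' Moving least-squares polynomial smoothing, applied per contiguous axis
#' segment. Interior points take the value at the center of a degree-`order`
#' fit over `window` points; the `(window-1)/2` points at each segment edge
#' are fitted on the truncated one-sided window. Polynomials up to the fit
#' order are reproduced exactly. `passes` sequential applications.
#'
#' @param s A `spectrum`.
#' @param window Odd window length in points, > `order`.
#' @param order Polynomial degree.
#' @param passes Number of passes (>= 1).
#' @return The smoothed `spectrum`.
#' @export
savitzky_golay <- function(s, window = 25, order = 2, passes = 2) {
  stopifnot(inherits(s, "spectrum"))
  if (window %% 2 != 1 || window <= order)
    stop("window must be odd and greater than order", call. = FALSE)
  y <- s$intensities
  for (ix in axis_segments(s$axis))
    y[ix] <- sg_segment(s$intensities[ix], window, order, passes)
  m <- s$meta
  new_spectrum(s$axis, y, m$spectrum_id, m$day, m$session, m$replicate)
}

#' Standard normal variate normalization
#'
#' Per-spectrum standardisation to zero mean and unit sample standard
#' deviation (n-1 denominator), computed jointly over all retained points.
#' Removes multiplicative scatter/scale and additive offset effects.
#'
#' @param s A `spectrum`.
#' @return The normalized `spectrum`.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  y <- s$intensities
  if (length(y) < 2) stop("SNV needs at least 2 points", call. = FALSE)
  sdev <- stats::sd(y)
  if (sdev == 0)
    stop(sprintf("spectrum %s is constant; SNV is undefined", s$meta$spectrum_id),
         call. = FALSE)
  m <- s$meta
  new_spectrum(s$axis, (y - mean(y)) / sdev, m$spectrum_id, m$day, m$session,
               m$replicate)
}

#' Run the full pre-processing chain over a spectra set
#'
#' Applies, in order: crop to the retained ranges, concave rubberband
#' baseline correction, Savitzky-Golay smoothing, SNV normalization —
#' the standard chain for fluorescence-dominated culture spectra. Metadata
#' are preserved. A per-stage summary (points retained, mean fraction of
#' intensity removed as baseline) is attached as attribute `"log"`.
#'
#' @param set A `spectra_set`.
#' @param params A [preprocess_params()].
#' @return The pre-processed `spectra_set`.
#' @export
preprocess <- function(set, params = preprocess_params()) {
  stopifnot(inherits(set, "spectra_set"), inherits(params, "preprocess_params"))
  cropped <- crop(set, params$ranges)
  segs <- axis_segments(cropped$axis)
  out <- cropped$matrix
  baseline_frac <- numeric(n_spectra(set))
  for (i in seq_len(nrow(out))) {
    y <- cropped$matrix[i, ]
    id <- cropped$meta$spectrum_id[i]
    res <- tryCatch({
      b <- numeric(length(y))
      for (ix in segs)
        b[ix] <- rubberband_segment(cropped$axis[ix], y[ix],
                                    params$bend_angle, params$n_baseline_iter)
      yc <- y - b
      for (ix in segs)
        yc[ix] <- sg_segment(yc[ix], params$sg_window, params$sg_order,
                             params$sg_passes)
      sdev <- stats::sd(yc)
      if (sdev == 0) stop("constant after baseline removal; SNV undefined")
      list(y = (yc - mean(yc)) / sdev,
           bf = sum(abs(b)) / max(sum(abs(y)), .Machine$double.eps))
    }, error = function(e)
      stop(sprintf("preprocess failed for spectrum %s: %s", id,
                   conditionMessage(e)), call. = FALSE))
    out[i, ] <- res$y
    baseline_frac[i] <- res$bf
  }
  result <- new_spectra_set(cropped$axis, out, cropped$meta)
  attr(result, "log") <- list(
    points_in = length(set$axis), points_retained = length(cropped$axis),
    segments = length(segs),
    mean_baseline_fraction = mean(baseline_frac))
  result
}
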