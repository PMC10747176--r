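#' Built-in vibrational band assignments
#'
#' The assigned bands of nitrogen-starved green microalgae used throughout
#' the kinetic analysis: carbohydrate skeletal deformation (479), the
#' phospholipid choline head group (865), chlorophyll CH3 deformation (988),
#' the resonance-enhanced carotenoid C-C and C=C stretches (1157, 1524),
#' the acyl CH2 scissor (1444), cis C=C stretch (1660), ester carbonyl of
#' triacylglycerols (1750), and the C-H stretch manifold (2850, 2885, 2940,
#' 2970) with the olefinic =C-H stretch (3008).
#'
#' @param path Optional path to a user table (tab-separated with columns
#'   label, center, mode, molecule_class) overriding the built-in one.
#' @return data.frame with columns label, center, mode, molecule_class.
#' @export
band_assignments <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "band_assignments.tsv", package = "ramalgae",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "center", "mode", "molecule_class")
  if (!all(need %in% names(tab)))
    stop("assignment table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$label))
    stop("assignment labels must be unique", call. = FALSE)
  tab$label <- as.character(tab$label)
  tab
}

#' Built-in named band ratios
#'
#' `unsaturation_index` (1660/1444) tracks unsaturated-to-saturated fatty
#' acid balance; `carotenoid_ratio` (1157/1524) tracks the relative weight
#' of the two resonance carotenoid stretches.
#'
#' @return data.frame with columns label, numerator, denominator.
#' @export
band_ratios <- function() {
  data.frame(label = c("unsaturation_index", "carotenoid_ratio"),
             numerator = c("1660", "1157"),
             denominator = c("1444", "1524"),
             stringsAsFactors = FALSE)
}

resolve_band <- function(band, table = band_assignments()) {
  if (is.list(band) && !is.null(band$center)) return(band)
  i <- match(as.character(band), table$label)
  if (is.na(i))
    stop(sprintf("unknown band '%s'; known labels: %s", band,
                 paste(table$label, collapse = ", ")), call. = FALSE)
  as.list(table[i, ])
}

band_window_idx <- function(axis, center, half_window) {
  ix <- which(axis >= center - half_window & axis <= center + half_window)
  if (!length(ix))
    stop(sprintf("band window [%g, %g] cm^-1 falls outside the axis",
                 center - half_window, center + half_window), call. = FALSE)
  ix
}

#' Band intensity of one spectrum
#'
#' Intensity of an assigned band, read as the maximum within
#' `center +/- half_window` (robust to small calibration drift at 10 cm^-1
#' instrument resolution), or optionally the trapezoidal area over the
#' window. On SNV-normalized spectra values may be negative; they remain
#' comparable across spectra because all sit on the same normalized scale.
#'
#' @param s A `spectrum`.
#' @param band A label from [band_assignments()] or a list with a `center`
#'   field (cm^-1).
#' @param half_window Half window in cm^-1 (default 8).
#' @param stat `"max"` (default) or `"area"`.
#' @return Numeric intensity.
#' @export
band_intensity <- function(s, band, half_window = 8, stat = c("max", "area")) {
  stat <- match.arg(stat)
  b <- resolve_band(band)
  ix <- band_window_idx(s$axis, b$center, half_window)
  if (stat == "max") max(s$intensities[ix])
  else if (length(ix) > 1)
    sum(diff(s$axis[ix]) * (s$intensities[ix][-1] + s$intensities[ix][-length(ix)]) / 2)
  else s$intensities[ix]
}

#' Ratio of two band intensities
#'
#' Computed per spectrum so common multiplicative factors (focus, turbidity,
#' laser fluctuations) cancel. A zero denominator yields `NA` with a warning
#' rather than a silent infinity.
#'
#' @param s A `spectrum`.
#' @param num,den Numerator and denominator bands (labels or lists with
#'   `center`).
#' @param half_window Half window in cm^-1.
#' @param stat Passed to [band_intensity()].
#' @return Numeric ratio, `NA` if the denominator intensity is 0.
#' @export
band_ratio <- function(s, num, den, half_window = 8, stat = "max") {
  d <- band_intensity(s, den, half_window, stat)
  if (d == 0) {
    warning("zero denominator band intensity; ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  band_intensity(s, num, half_window, stat) / d
}

quantity_fun <- function(quantity, half_window, stat,
                         table = band_assignments()) {
  ratios <- band_ratios()
  if (quantity %in% ratios$label) {
    r <- ratios[ratios$label == quantity, ]
    num <- resolve_band(r$numerator, table)
    den <- resolve_band(r$denominator, table)
    function(s) band_ratio(s, num, den, half_window, stat)
  } else if (quantity %in% table$label) {
    b <- resolve_band(quantity, table)
    function(s) band_intensity(s, b, half_window, stat)
  } else {
    stop(sprintf("unknown quantity '%s'; known labels: %s", quantity,
                 paste(c(table$label, ratios$label), collapse = ", ")),
         call. = FALSE)
  }
}

#' Kinetic series of a band intensity or ratio over culture days
#'
#' Per-day mean, standard deviation and count of the per-spectrum quantity —
#' the trace plotted when following pigment decline or storage-lipid
#' accumulation through a culture run.
#'
#' @param set A `spectra_set` (pre-processed).
#' @param quantity A band label (e.g. `"1524"`) or named ratio
#'   (`"unsaturation_index"`, `"carotenoid_ratio"`).
#' @param half_window Half window in cm^-1 (default 8).
#' @param stat `"max"` or `"area"`.
#' @param table Assignment table (defaults to the built-in one).
#' @return data.frame with columns day, mean, sd, n and attribute
#'   `"quantity"`; days ascending.
#' @export
kinetic_series <- function(set, quantity, half_window = 8, stat = "max",
                           table = band_assignments()) {
  stopifnot(inherits(set, "spectra_set"))
  f <- quantity_fun(quantity, half_window, stat, table)
  vals <- vapply(seq_len(n_spectra(set)), function(i) f(get_spectrum(set, i)), 0)
  days <- sort(unique(set$meta$day))
  out <- do.call(rbind, lapply(days, function(d) {
    v <- vals[set$meta$day == d]
    data.frame(day = d, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v))
  }))
  attr(out, "quantity") <- quantity
  out
}
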