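#' Construct a single Raman spectrum
#'
#' A `spectrum` couples a strictly ascending wavenumber axis (cm^-1) with one
#' intensity trace and acquisition metadata (culture day, session, replicate).
#'
#' @param axis Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @param intensities Numeric vector, same length as `axis`.
#' @param spectrum_id Character scalar identifier.
#' @param day Integer culture-day index (0-based).
#' @param session Integer acquisition-session index within the day (0-based).
#' @param replicate Integer replicate index within the session (0-based).
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(axis, intensities, spectrum_id = "s0",
                         day = 0L, session = 0L, replicate = 0L) {
  axis <- as.numeric(axis)
  intensities <- as.numeric(intensities)
  if (length(axis) != length(intensities))
    stop("axis and intensities must have equal length", call. = FALSE)
  if (length(axis) && any(diff(axis) <= 0))
    stop("axis must be strictly increasing", call. = FALSE)
  if (!all(is.finite(axis)) || !all(is.finite(intensities)))
    stop("spectrum values must be finite", call. = FALSE)
  structure(
    list(axis = axis, intensities = intensities,
         meta = data.frame(spectrum_id = as.character(spectrum_id),
                           day = as.integer(day), session = as.integer(session),
                           replicate = as.integer(replicate),
                           stringsAsFactors = FALSE)),
    class = "spectrum")
}

#' Construct a set of spectra on a shared axis
#'
#' The `spectra_set` is the unit flowing through the pipeline: an
#' n_spectra x n_points intensity matrix, the common wavenumber axis, and a
#' per-spectrum metadata table (spectrum_id, day, session, replicate).
#'
#' @param axis Shared wavenumber axis (cm^-1), strictly increasing.
#' @param matrix Numeric matrix, one row per spectrum, `length(axis)` columns.
#' @param meta data.frame with columns spectrum_id, day, session, replicate;
#'   one row per matrix row; spectrum_id unique.
#' @return An object of class `spectra_set`.
#' @export
new_spectra_set <- function(axis, matrix, meta) {
  axis <- as.numeric(axis)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (length(axis) && any(diff(axis) <= 0))
    stop("axis must be strictly increasing", call. = FALSE)
  if (ncol(matrix) != length(axis))
    stop("matrix column count must equal axis length", call. = FALSE)
  need <- c("spectrum_id", "day", "session", "replicate")
  if (!all(need %in% names(meta)))
    stop("meta must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(meta) != nrow(matrix))
    stop("meta row count must equal matrix row count", call. = FALSE)
  if (anyDuplicated(meta$spectrum_id))
    stop("spectrum_id values must be unique", call. = FALSE)
  if (any(meta$day < 0))
    stop("day indices must be non-negative", call. = FALSE)
  meta <- data.frame(spectrum_id = as.character(meta$spectrum_id),
                     day = as.integer(meta$day),
                     session = as.integer(meta$session),
                     replicate = as.integer(meta$replicate),
                     stringsAsFactors = FALSE)
  rownames(matrix) <- meta$spectrum_id
  structure(list(axis = axis, matrix = matrix, meta = meta),
            class = "spectra_set")
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(set) nrow(set$matrix)

#' Extract one spectrum from a set
#' @param set A `spectra_set`.
#' @param i Row index or spectrum_id.
#' @return A `spectrum`.
#' @export
get_spectrum <- function(set, i) {
  if (is.character(i)) i <- match(i, set$meta$spectrum_id)
  if (is.na(i) || i < 1 || i > n_spectra(set))
    stop("no such spectrum in set", call. = FALSE)
  m <- set$meta[i, ]
  new_spectrum(set$axis, set$matrix[i, ], m$spectrum_id, m$day, m$session,
               m$replicate)
}

#' Subset a spectra set by row indices
#' @param set A `spectra_set`.
#' @param idx Integer row indices (or logical mask).
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(set, idx) {
  new_spectra_set(set$axis, set$matrix[idx, , drop = FALSE], set$meta[idx, ])
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> day %d session %d replicate %d | %d points, %.0f-%.0f cm^-1\n",
              x$meta$spectrum_id, x$meta$day, x$meta$session, x$meta$replicate,
              length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points | %.0f-%.0f cm^-1 | days %d-%d\n",
              nrow(x$matrix), ncol(x$matrix), min(x$axis), max(x$axis),
              min(x$meta$day), max(x$meta$day)))
  invisible(x)
}

# Contiguous-segment index ranges of an axis that may contain crop gaps.
# A gap is any step larger than `gap_factor` times the median step.
axis_segments <- function(axis, gap_factor = 2.5) {
  if (length(axis) < 2) return(list(seq_along(axis)))
  d <- diff(axis)
  breaks <- which(d > gap_factor * stats::median(d))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(axis))
  Map(seq.int, starts, ends)
}
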