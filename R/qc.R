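#' All-pairs spectral correlation map
#'
#' Pearson correlation of every pair of (pre-processed) spectra over all
#' retained points, the standard quick look at spectral quality over a
#' campaign: blocks of high correlation mark physiologically homogeneous
#' phases. Spectra are ordered by (day, session, replicate).
#'
#' @param set A `spectra_set` (pre-processed).
#' @return A `correlation_map`: list with `matrix` (symmetric, unit
#'   diagonal), `order` (spectrum ids), `day_boundaries` (per-day index
#'   ranges), and `overall` (mean/sd over the strict upper triangle).
#' @export
correlation_map <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (n_spectra(set) < 2)
    stop("correlation map needs at least 2 spectra", call. = FALSE)
  sds <- apply(set$matrix, 1, stats::sd)
  if (any(sds == 0))
    stop("constant spectrum (undefined correlation): ",
         paste(set$meta$spectrum_id[sds == 0], collapse = ", "), call. = FALSE)
  o <- order(set$meta$day, set$meta$session, set$meta$replicate)
  set <- subset_spectra(set, o)
  cm <- stats::cor(t(set$matrix))
  diag(cm) <- 1
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]  # enforce exact symmetry
  days <- sort(unique(set$meta$day))
  bounds <- lapply(days, function(d) range(which(set$meta$day == d)))
  names(bounds) <- days
  ut <- cm[upper.tri(cm)]
  structure(list(matrix = cm, order = set$meta$spectrum_id,
                 meta = set$meta, day_boundaries = bounds,
                 overall = c(mean = mean(ut), sd = stats::sd(ut))),
            class = "correlation_map")
}

day_groups <- function(meta, pool_sessions = TRUE) {
  if (pool_sessions) split(seq_len(nrow(meta)), meta$day)
  else split(seq_len(nrow(meta)), interaction(meta$day, meta$session, drop = TRUE))
}

#' Per-day repeatability of spectra
#'
#' For each culture day, the mean and standard deviation of the m(m-1)/2
#' within-day pairwise Pearson correlations (self-pairs excluded). High,
#' stable values indicate reproducible acquisitions; drops flag phases of
#' physiological heterogeneity.
#'
#' @param set A `spectra_set` (pre-processed).
#' @param pool_sessions Pool all sessions of a calendar day (default). With
#'   `FALSE`, each day/session cell is summarised separately.
#' @return data.frame with columns day, mean, sd, n_pairs. Days with fewer
#'   than 2 spectra get NA mean/sd and n_pairs = 0.
#' @export
repeatability <- function(set, pool_sessions = TRUE) {
  cm <- correlation_map(set)
  grp <- day_groups(cm$meta, pool_sessions)
  res <- lapply(names(grp), function(g) {
    ix <- grp[[g]]
    m <- length(ix)
    if (m < 2)
      return(data.frame(day = cm$meta$day[ix[1]], mean = NA_real_,
                        sd = NA_real_, n_pairs = 0L))
    sub <- cm$matrix[ix, ix]
    v <- sub[upper.tri(sub)]
    data.frame(day = cm$meta$day[ix[1]], mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0, n_pairs = length(v))
  })
  out <- do.call(rbind, res)
  out[order(out$day), , drop = FALSE]
}

#' Similarity of each day to a reference day
#'
#' For each culture day, the mean and standard deviation of all cross-pair
#' correlations between that day's spectra and the reference day's spectra
#' (the first day in a campaign is the usual reference). A declining series
#' quantifies how far the culture has drifted from its initial state.
#'
#' @param set A `spectra_set` (pre-processed).
#' @param reference_day Day index used as reference (default 0).
#' @return data.frame with columns day, mean, sd, n_pairs, reference_day.
#'   For the reference day itself, cross-pairs exclude self-pairs.
#' @export
similarity_to_reference <- function(set, reference_day = 0) {
  cm <- correlation_map(set)
  ref <- which(cm$meta$day == reference_day)
  if (!length(ref))
    stop(sprintf("reference day %d has no spectra", reference_day), call. = FALSE)
  grp <- day_groups(cm$meta, pool_sessions = TRUE)
  res <- lapply(grp, function(ix) {
    d <- cm$meta$day[ix[1]]
    if (d == reference_day) {
      sub <- cm$matrix[ix, ix]
      v <- sub[upper.tri(sub)]
    } else {
      v <- as.vector(cm$matrix[ix, ref])
    }
    data.frame(day = d, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n_pairs = length(v), reference_day = as.integer(reference_day))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$day), , drop = FALSE]
}

#' Pointwise median spectrum of one day
#'
#' The robust daily summary spectrum (even counts use the midpoint of the
#' two central values).
#'
#' @param set A `spectra_set`.
#' @param day Day index.
#' @return A `spectrum` with id `"median_d<day>"`.
#' @export
median_spectrum <- function(set, day) {
  ix <- which(set$meta$day == day)
  if (!length(ix))
    stop(sprintf("day %d has no spectra", day), call. = FALSE)
  med <- apply(set$matrix[ix, , drop = FALSE], 2, stats::median)
  new_spectrum(set$axis, med, sprintf("median_d%02d", day), day = day)
}
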