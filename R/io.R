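#' Write a spectra set to a delimited text file
#'
#' One header line (`spectrum_id  day  session  replicate` followed by the
#' wavenumber axis), then one row per spectrum. Tab-separated, UTF-8, '.'
#' decimal. Values round-trip through [read_spectra()] to full double
#' precision.
#'
#' @param set A `spectra_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  dt <- data.table::data.table(set$meta, set$matrix)
  data.table::setnames(dt, c(names(set$meta), format(set$axis, trim = TRUE,
                                                     digits = 12)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a spectra set from a delimited text file
#'
#' Inverse of [write_spectra()]. Malformed input (ragged rows, non-numeric
#' intensity cells, duplicate ids) is rejected with the offending line
#' reported.
#'
#' @param path Input file path.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header))
    stop("no header: ", path, call. = FALSE)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  need <- c("spectrum_id", "day", "session", "replicate")
  if (length(cols) <= 4 || !identical(cols[1:4], need))
    stop("header must start with spectrum_id, day, session, replicate followed by the wavenumber axis",
         call. = FALSE)
  axis <- suppressWarnings(as.numeric(cols[-(1:4)]))
  if (anyNA(axis)) stop("non-numeric wavenumber in header", call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, fill = TRUE,
                          colClasses = list(character = 1L))
  if (ncol(dt) != length(cols))
    stop("rows have inconsistent field counts", call. = FALSE)
  vals <- as.matrix(dt[, -(1:4)])
  if (is.character(vals)) {
    bad <- which(apply(vals, 1, function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop("non-numeric intensity cell at line ", bad[1] + 1L, call. = FALSE)
  }
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))
    stop("missing or malformed intensities at line ", bad[1] + 1L,
         " (expected ", length(axis), " values)", call. = FALSE)
  }
  meta <- data.frame(spectrum_id = dt[[1]], day = as.integer(dt[[2]]),
                     session = as.integer(dt[[3]]),
                     replicate = as.integer(dt[[4]]), stringsAsFactors = FALSE)
  if (anyDuplicated(meta$spectrum_id))
    stop("duplicate spectrum_id: ",
         meta$spectrum_id[duplicated(meta$spectrum_id)][1], call. = FALSE)
  new_spectra_set(axis, vals, meta)
}

#' Write a run configuration as structured text (YAML)
#' @param config A list (e.g. [simulation_config()] or a full run config).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' Read a run configuration from structured text (YAML)
#' @param path Input path.
#' @return A list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
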