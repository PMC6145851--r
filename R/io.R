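#' Read and write parcellated time series as TSV
#'
#' The on-disk format is tab-delimited text with a header row of region
#' labels and one row per frame. `writeTimeSeries` prints doubles with 17
#' significant digits so a read/write round trip is lossless.
#'
#' @param path file path.
#' @param tr repetition time in seconds (not stored in the TSV).
#' @param runMeta optional named list of metadata attached to the result.
#' @return `readTimeSeries` returns a [ParcellatedTimeSeries-class];
#'   `writeTimeSeries` returns `path` invisibly.
#' @export
readTimeSeries <- function(path, tr, runMeta = list()) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicate region labels in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  ncols <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != ncols))
    stop(sprintf("ragged row in %s: data row %d has %d fields, expected %d",
                 path, which(lens != ncols)[1], lens[lens != ncols][1], ncols))
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1] - 1L
    stop(sprintf("non-numeric or missing cell in %s at data row %d, column %d (label '%s')",
                 path, bad %/% ncols + 1L, bad %% ncols + 1L,
                 header[bad %% ncols + 1L]))
  }
  X <- matrix(vals, nrow = length(rows), ncol = ncols, byrow = TRUE)
  ParcellatedTimeSeries(X, tr = tr, regionLabels = header, runMeta = runMeta)
}

#' @rdname readTimeSeries
#' @param ts a [ParcellatedTimeSeries-class].
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "ParcellatedTimeSeries"))
  X <- tsData(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(regionLabels(ts), collapse = "\t"), con)
  body <- apply(X, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read rigid-body motion parameters
#'
#' Whitespace-delimited text, six columns per frame: three translations (mm)
#' then three rotations (radians), the realignment-parameter dialect.
#'
#' @param path file path.
#' @return frames x 6 numeric matrix.
#' @export
readMotionParams <- function(path) {
  mp <- as.matrix(read.table(path, header = FALSE))
  if (ncol(mp) != 6L)
    stop("motion parameter file must have 6 columns, found ", ncol(mp))
  storage.mode(mp) <- "double"
  colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  mp
}

#' Read a pupil trace
#'
#' Delimited text with columns time (s), diameter, and optionally a 0/1
#' artifact column. The sampling rate is inferred from the median time step.
#'
#' @param path file path.
#' @return list with `pupil` (a [PupilSeries-class]) and `artifactMask`
#'   (logical, TRUE where the sample is an artifact).
#' @export
readPupil <- function(path) {
  d <- read.table(path, header = TRUE)
  if (ncol(d) < 2L) stop("pupil file needs at least time and diameter columns")
  rate <- 1 / median(diff(d[[1]]))
  mask <- if (ncol(d) >= 3L) as.logical(d[[3]]) else rep(FALSE, nrow(d))
  list(pupil = PupilSeries(d[[2]], rate = rate), artifactMask = mask)
}
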