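#' ParcellatedTimeSeries: region-wise BOLD signals for one run
#'
#' The pipeline's entry point: a frames x regions matrix of parcel-mean BOLD
#' signal together with the repetition time and region labels. Run-level
#' metadata (subject, session, condition) travels in `runMeta`.
#'
#' @slot data numeric matrix, frames x regions, no missing values.
#' @slot tr repetition time in seconds.
#' @slot regionLabels unique region names, one per column.
#' @slot runMeta named list of run-level metadata strings.
#' @export
setClass("ParcellatedTimeSeries",
  representation(data = "matrix", tr = "numeric",
                 regionLabels = "character", runMeta = "list"))

setValidity("ParcellatedTimeSeries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be numeric")
  if (anyNA(d)) return("data contains missing values")
  if (ncol(d) < 2L) return("need at least 2 regions")
  if (nrow(d) < 3L) return("need at least 3 frames")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a single positive number (seconds)")
  if (length(object@regionLabels) != ncol(d))
    return("one region label per column required")
  if (anyDuplicated(object@regionLabels))
    return("region labels must be unique")
  TRUE
})

#' Construct a ParcellatedTimeSeries
#'
#' @param data frames x regions numeric matrix.
#' @param tr repetition time in seconds.
#' @param regionLabels region names; defaults to column names or `R1..RN`.
#' @param runMeta named list of metadata (subject, session, condition, ...).
#' @return a [ParcellatedTimeSeries-class] object.
#' @export
ParcellatedTimeSeries <- function(data, tr, regionLabels = NULL,
                                  runMeta = list()) {
  data <- as.matrix(data)
  if (is.null(regionLabels))
    regionLabels <- colnames(data)
  if (is.null(regionLabels))
    regionLabels <- paste0("R", seq_len(ncol(data)))
  colnames(data) <- regionLabels
  new("ParcellatedTimeSeries", data = data, tr = as.numeric(tr),
      regionLabels = as.character(regionLabels), runMeta = runMeta)
}

#' MTDTensor: time-resolved coupling array
#'
#' Signed weighted coupling between all region pairs in each sliding window,
#' as produced by [mtdCoupling()]. `windowCenters` are centres on the
#' derivative-sample grid (derivative sample t sits between frames t and
#' t + 1).
#'
#' @slot coupling regions x regions x windows array.
#' @slot window window length in frames.
#' @slot stride window step in frames.
#' @slot windowCenters numeric centre of each window on the derivative grid.
#' @slot regionLabels region names.
#' @slot tr repetition time in seconds.
#' @export
setClass("MTDTensor",
  representation(coupling = "array", window = "integer", stride = "integer",
                 windowCenters = "numeric", regionLabels = "character",
                 tr = "numeric"))

setValidity("MTDTensor", function(object) {
  d <- dim(object@coupling)
  if (length(d) != 3L) return("coupling must be a 3-d array")
  if (d[1] != d[2]) return("coupling must be square in its first two dims")
  if (d[1] != length(object@regionLabels))
    return("regionLabels length must match coupling dimension")
  if (d[3] != length(object@windowCenters))
    return("one window centre per window required")
  TRUE
})

#' WindowPartitionSet: per-window module assignments
#'
#' Module assignments `Ci_T`, modularity `Q_T` and module counts for every
#' temporal window, as produced by [runWindows()]. `matched` records whether
#' labels have been made temporally consistent by [matchLabels()].
#'
#' @slot assignments windows x regions integer matrix of module ids
#'   (contiguous, 1-based within each window).
#' @slot Q per-window signed modularity.
#' @slot nModules per-window module count.
#' @slot gamma resolution parameter used.
#' @slot matched logical: labels matched across windows.
#' @slot regionLabels region names.
#' @export
setClass("WindowPartitionSet",
  representation(assignments = "matrix", Q = "numeric", nModules = "integer",
                 gamma = "numeric", matched = "logical",
                 regionLabels = "character"))

setValidity("WindowPartitionSet", function(object) {
  a <- object@assignments
  if (nrow(a) != length(object@Q)) return("one Q per window required")
  if (nrow(a) != length(object@nModules)) return("one module count per window")
  if (any(!is.finite(object@Q))) return("Q must be finite")
  if (ncol(a) != length(object@regionLabels))
    return("one region label per column required")
  TRUE
})

#' TopologySeries: per-window regional cartography
#'
#' Participation coefficient `B` (between-module connectivity, in \[0, 1\])
#' and module-degree z-score `W` (within-module connectivity) for every
#' region and window, plus the per-window mean participation.
#'
#' @slot B windows x regions participation coefficients.
#' @slot W windows x regions module-degree z-scores.
#' @slot meanB per-window mean of `B` across regions.
#' @slot regionLabels region names.
#' @export
setClass("TopologySeries",
  representation(B = "matrix", W = "matrix", meanB = "numeric",
                 regionLabels = "character"))

setValidity("TopologySeries", function(object) {
  if (!all(dim(object@B) == dim(object@W)))
    return("B and W must have identical shape")
  if (nrow(object@B) != length(object@meanB))
    return("one meanB per window required")
  if (any(object@B < -1e-9 | object@B > 1 + 1e-9))
    return("participation coefficients must lie in [0, 1]")
  if (any(!is.finite(object@W))) return("W must be finite")
  TRUE
})

#' CartographicProfile: joint (B, W) occupancy histogram
#'
#' Two-dimensional histogram of participation coefficient against
#' module-degree z-score, pooled over regions and windows; occupancy is a
#' proportion and sums to one. Samples outside the W range are clipped into
#' the edge bins and counted in `nClipped`.
#'
#' @slot occupancy nB x nW matrix of bin proportions.
#' @slot bEdges,wEdges strictly increasing bin edges.
#' @slot nClipped number of samples clipped into edge bins.
#' @export
setClass("CartographicProfile",
  representation(occupancy = "matrix", bEdges = "numeric", wEdges = "numeric",
                 nClipped = "integer"))

setValidity("CartographicProfile", function(object) {
  if (abs(sum(object@occupancy) - 1) > 1e-9)
    return("occupancy must sum to 1")
  if (any(diff(object@bEdges) <= 0) || any(diff(object@wEdges) <= 0))
    return("bin edges must be strictly increasing")
  if (nrow(object@occupancy) != length(object@bEdges) - 1L ||
      ncol(object@occupancy) != length(object@wEdges) - 1L)
    return("occupancy shape must match bin edges")
  TRUE
})

#' PupilSeries: pupil diameter trace
#'
#' @slot samples pupil diameter values.
#' @slot rate sampling rate in Hz.
#' @slot interpolatedMask logical, TRUE where the value was interpolated.
#' @slot zScored logical flag.
#' @export
setClass("PupilSeries",
  representation(samples = "numeric", rate = "numeric",
                 interpolatedMask = "logical", zScored = "logical"))

setValidity("PupilSeries", function(object) {
  if (length(object@samples) != length(object@interpolatedMask))
    return("mask length must equal samples length")
  if (object@rate <= 0) return("rate must be positive")
  TRUE
})

#' @rdname PupilSeries-class
#' @param samples,rate,interpolatedMask,zScored see slots.
#' @export
PupilSeries <- function(samples, rate,
                        interpolatedMask = rep(FALSE, length(samples)),
                        zScored = FALSE) {
  new("PupilSeries", samples = as.numeric(samples), rate = as.numeric(rate),
      interpolatedMask = as.logical(interpolatedMask), zScored = zScored)
}

#' VarModel: stationary vector-autoregressive surrogate model
#'
#' Least-squares VAR fit (optionally in a principal subspace) whose simulated
#' stationary covariance is matched to the empirical covariance of the data
#' it was fit to; used to generate linear, stationary surrogate time series.
#'
#' @slot order VAR order p.
#' @slot coefs d x d x p array of lag coefficient matrices (subspace scale).
#' @slot innovChol upper Cholesky factor of the innovation covariance.
#' @slot transform d x d map applied to simulated series so their stationary
#'   covariance equals the empirical (subspace) covariance.
#' @slot projection regions x d principal-subspace basis (identity when no
#'   reduction was applied).
#' @slot complementSd per-region sd of white noise restoring variance lost
#'   to the subspace projection.
#' @slot mean per-region mean of the training data.
#' @slot empCov empirical covariance matched by the surrogates.
#' @slot regionLabels region names.
#' @slot tr repetition time in seconds.
#' @export
setClass("VarModel",
  representation(order = "integer", coefs = "array", innovChol = "matrix",
                 transform = "matrix", projection = "matrix",
                 complementSd = "numeric", mean = "numeric",
                 empCov = "matrix", regionLabels = "character",
                 tr = "numeric"))
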