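#' First temporal derivative of a parcellated time series
#'
#' Backward first difference per region, with the per-region standard
#' deviation of the full derivative series (population convention) used to
#' standardise coupling. A region whose derivative is constant has no
#' coupling scale and triggers an error naming it.
#'
#' @param ts a [ParcellatedTimeSeries-class] with at least 3 frames.
#' @return list with `d` ((frames-1) x regions derivative matrix) and
#'   `sigma` (per-region sd of the derivative).
#' @export
temporalDerivative <- function(ts) {
  stopifnot(is(ts, "ParcellatedTimeSeries"))
  X <- tsData(ts)
  if (nrow(X) < 3L) stop("need at least 3 frames")
  D <- diff(X)
  sigma <- apply(D, 2, popSd)
  if (any(sigma == 0)) {
    bad <- regionLabels(ts)[sigma == 0]
    stop("constant derivative (sigma = 0) in region(s): ",
         paste(bad, collapse = ", "))
  }
  list(d = D, sigma = sigma)
}

#' Multiplication of temporal derivatives (MTD) coupling tensor
#'
#' Time-resolved functional connectivity: for every region pair the
#' standardised product of first temporal derivatives, averaged over a
#' sliding window of `w` frames,
#' `MTD_ijt = (1/w) * sum_window dt_i dt_j / (sigma_i sigma_j)`.
#' Windows are full ("valid") only: the first window covers derivative
#' samples 1..w, and with stride 1 there are `(frames - 1) - w + 1` windows.
#' The tensor is symmetric in its first two dimensions with non-negative
#' diagonal (a region's windowed derivative variance).
#'
#' @param ts a [ParcellatedTimeSeries-class] with at least `w + 2` frames.
#' @param w window length in frames (default 15, about 33 s at TR 2.2 s).
#' @param stride window step in frames.
#' @return an [MTDTensor-class].
#' @export
mtdCoupling <- function(ts, w = 15L, stride = 1L) {
  stopifnot(is(ts, "ParcellatedTimeSeries"))
  w <- as.integer(w); stride <- as.integer(stride)
  if (nFrames(ts) < w + 2L)
    stop("need at least w + 2 = ", w + 2L, " frames, have ", nFrames(ts))
  der <- temporalDerivative(ts)
  D <- sweep(der$d, 2, der$sigma, "/")
  arr <- cpp_mtd(D, w, stride)
  nw <- dim(arr)[3]
  centers <- (seq_len(nw) - 1L) * stride + (w + 1) / 2
  new("MTDTensor", coupling = arr, window = w, stride = stride,
      windowCenters = centers, regionLabels = regionLabels(ts),
      tr = trSeconds(ts))
}

#' Frame windows spanned by each MTD window
#'
#' Utility for aligning frame-level covariates (pupil, task regressors,
#' motion) with the window grid: window k of an MTD tensor with stride 1
#' spans derivative samples k..k+w-1, i.e. original frames k..k+w. Returns
#' the covariate averaged over the frames of each window.
#'
#' @param x per-frame numeric vector or frames x p matrix.
#' @param tensor an [MTDTensor-class] (or anything with the same window
#'   geometry: pass `w`, `stride`, `nWindows` explicitly instead).
#' @param w,stride,n window geometry when `tensor` is missing.
#' @return windows x p matrix (or vector when `x` is a vector).
#' @export
windowAverage <- function(x, tensor = NULL, w = NULL, stride = 1L, n = NULL) {
  if (!is.null(tensor)) {
    w <- tensor@window; stride <- tensor@stride; n <- nWindows(tensor)
  }
  vec <- is.null(dim(x))
  X <- as.matrix(x)
  out <- matrix(NA_real_, n, ncol(X))
  for (k in seq_len(n)) {
    fr <- ((k - 1L) * stride + 1L):((k - 1L) * stride + w + 1L)
    fr <- fr[fr <= nrow(X)]
    out[k, ] <- colMeans(X[fr, , drop = FALSE])
  }
  if (vec) out[, 1] else out
}
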