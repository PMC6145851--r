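# Butterworth coefficients + a matrix-capable zero-phase filter. Columns are
# filtered forward and backward (squared magnitude response, zero phase)
# after odd-reflection padding at both ends.
butterCoefs <- function(type, cutoffHz, fs, order = 2) {
  wc <- cutoffHz / (fs / 2)
  bf <- signal::butter(order, wc, type = type)
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

iirFilterMat <- function(b, a, X) {
  cpp_iir(b / a[1], a / a[1], X)
}

filtfiltMat <- function(b, a, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  pad <- min(n - 2L, max(3L * (max(length(a), length(b)) - 1L), 24L))
  top <- 2 * matrix(X[1, ], pad, ncol(X), byrow = TRUE) -
    X[pad + 1L - seq_len(pad) + 1L, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[n - seq_len(pad), , drop = FALSE]
  Y <- rbind(top, X, bot)
  Y <- iirFilterMat(b, a, Y)
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y <- iirFilterMat(b, a, Y)
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[pad + seq_len(n), , drop = FALSE]
}

#' Temporal band-pass filter for parcellated time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied per region.
#' The defaults retain the 0.01-0.125 Hz band conventionally analysed in
#' resting-state connectivity work.
#'
#' @param ts a [ParcellatedTimeSeries-class].
#' @param low,high band edges in Hz; requires `0 < low < high < ` Nyquist.
#' @param order Butterworth order (applied twice, so the effective roll-off
#'   is doubled).
#' @return a filtered [ParcellatedTimeSeries-class] of the same shape.
#' @export
bandpassFilter <- function(ts, low = 0.01, high = 0.125, order = 2) {
  stopifnot(is(ts, "ParcellatedTimeSeries"))
  fs <- 1 / trSeconds(ts)
  nyq <- fs / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq)
    stop(sprintf("high edge %.4g Hz is at or above Nyquist (%.4g Hz)", high, nyq))
  co <- butterCoefs("pass", c(low, high), fs, order)
  Y <- filtfiltMat(co$b, co$a, tsData(ts))
  ParcellatedTimeSeries(Y, tr = trSeconds(ts),
                        regionLabels = regionLabels(ts), runMeta = runMeta(ts))
}

#' Framewise displacement from rigid-body motion parameters
#'
#' The Power convention: the sum of absolute backward differences of the six
#' realignment parameters, with rotations converted to arc length on a
#' sphere of `headRadius` mm. The first frame is 0 by convention.
#'
#' @param mp frames x 6 matrix (translations mm, rotations radians).
#' @param headRadius sphere radius in mm.
#' @return per-frame FD in mm.
#' @export
computeFD <- function(mp, headRadius = 50) {
  mp <- as.matrix(mp)
  stopifnot(ncol(mp) == 6L, nrow(mp) >= 2L)
  d <- abs(diff(mp))
  d[, 4:6] <- d[, 4:6] * headRadius
  c(0, rowSums(d))
}

#' DVARS: root-mean-square frame-to-frame signal change
#'
#' Expressed as percent of the run's global mean signal (so a threshold of
#' 2.5 means 2.5% of the mean); the first frame is 0 by convention. Requires
#' data on its acquired (positive-mean) scale unless the series is constant.
#'
#' @param ts a [ParcellatedTimeSeries-class].
#' @return per-frame DVARS in percent signal change.
#' @export
computeDVARS <- function(ts) {
  X <- tsData(ts)
  rms <- c(0, sqrt(rowMeans(diff(X)^2)))
  if (all(rms == 0)) return(rms)
  gm <- mean(X)
  if (gm <= 0)
    stop("DVARS as percent signal change needs a positive global mean signal")
  100 * rms / gm
}

#' Flag high-motion frames and runs
#'
#' A frame is flagged when either framewise displacement or DVARS exceeds
#' its threshold; a run is marked for exclusion when more than `excludeProp`
#' of its frames are flagged.
#'
#' @param fd per-frame FD (mm).
#' @param dvars per-frame DVARS (percent).
#' @param fdThresh FD threshold in mm.
#' @param dvarsThresh DVARS threshold in percent.
#' @param excludeProp run-exclusion proportion.
#' @return list with `mask` (logical per frame), `propFlagged`, and
#'   `exclude` (logical).
#' @export
flagFrames <- function(fd, dvars, fdThresh = 0.25, dvarsThresh = 2.5,
                       excludeProp = 0.10) {
  stopifnot(length(fd) == length(dvars))
  mask <- fd > fdThresh | dvars > dvarsThresh
  list(mask = mask, propFlagged = mean(mask), exclude = mean(mask) > excludeProp)
}

#' Censor flagged frames from a time series
#'
#' Removes flagged frames entirely (scrubbing). Provided for sensitivity
#' analyses; the default pipeline analyses uncensored data.
#'
#' @param ts a [ParcellatedTimeSeries-class].
#' @param mask logical per frame, TRUE = drop.
#' @return a [ParcellatedTimeSeries-class] with the flagged frames removed.
#' @export
censorFrames <- function(ts, mask) {
  stopifnot(length(mask) == nFrames(ts))
  ParcellatedTimeSeries(tsData(ts)[!mask, , drop = FALSE], tr = trSeconds(ts),
                        regionLabels = regionLabels(ts), runMeta = runMeta(ts))
}

#' Preprocess a raw pupil trace to the fMRI frame rate
#'
#' Artifact samples are replaced by shape-preserving piecewise-cubic
#' (monotone Hermite) interpolation, the trace is low-pass filtered at 5 Hz
#' (zero-phase Butterworth), z-scored, and resampled to one value per fMRI
#' frame by averaging the samples within each TR. Subjects with at least
#' half of their samples interpolated are flagged for exclusion.
#'
#' @param p a [PupilSeries-class] with `rate` > 10 Hz.
#' @param artifactMask logical per sample, TRUE = artifact.
#' @param tr fMRI repetition time in seconds.
#' @param lowpassHz low-pass edge in Hz.
#' @param excludeProp interpolation proportion triggering exclusion.
#' @return list with `pupil` (frame-rate, z-scored [PupilSeries-class]),
#'   `propInterpolated`, and `exclude`.
#' @export
preprocessPupil <- function(p, artifactMask = NULL, tr,
                            lowpassHz = 5, excludeProp = 0.5) {
  stopifnot(is(p, "PupilSeries"))
  if (p@rate <= 10) stop("pupil sampling rate must exceed 10 Hz")
  x <- p@samples
  n <- length(x)
  mask <- if (is.null(artifactMask)) p@interpolatedMask else as.logical(artifactMask)
  stopifnot(length(mask) == n)
  if (all(mask)) stop("artifact span covers the entire trace")
  if (any(mask)) {
    good <- which(!mask)
    f <- stats::splinefun(good, x[good], method = "monoH.FC")
    x[mask] <- f(which(mask))
  }
  co <- butterCoefs("low", lowpassHz, p@rate)
  x <- as.numeric(filtfiltMat(co$b, co$a, matrix(x, ncol = 1)))
  x <- (x - mean(x)) / popSd(x)
  perFrame <- max(1L, as.integer(round(p@rate * tr)))
  nFramesOut <- n %/% perFrame
  idx <- rep(seq_len(nFramesOut), each = perFrame)
  xf <- as.numeric(tapply(x[seq_along(idx)], idx, mean))
  prop <- mean(mask)
  list(pupil = PupilSeries(xf, rate = 1 / tr,
                           interpolatedMask = as.logical(
                             tapply(mask[seq_along(idx)], idx, any)),
                           zScored = TRUE),
       propInterpolated = prop, exclude = prop >= excludeProp)
}
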