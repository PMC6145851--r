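#' SyntheticSpec: recipe for modular BOLD-like time series
#'
#' Describes a zero-mean Gaussian process with a block (modular) instantaneous
#' covariance: within-module correlation `withinCoupling`, between-module
#' correlation given per state by `betweenCoupling`, with the active state
#' switching on frame boundaries according to `stateSequence`. Optional white
#' measurement noise and optional smoothing with a canonical double-gamma
#' haemodynamic kernel. Every state's target covariance must be positive
#' semidefinite; construction fails naming the offending state otherwise.
#'
#' @slot nRegions number of regions.
#' @slot moduleSizes sizes of the planted modules (sums to nRegions).
#' @slot tr repetition time in seconds.
#' @slot nFrames number of frames.
#' @slot withinCoupling within-module correlation in \[0, 1).
#' @slot betweenCoupling named vector: state label -> between-module
#'   correlation.
#' @slot stateSequence per-frame state labels.
#' @slot noiseSd sd of additive white noise (signal units).
#' @slot hrfSmoothing convolve with the double-gamma kernel.
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
  representation(nRegions = "integer", moduleSizes = "integer",
                 tr = "numeric", nFrames = "integer",
                 withinCoupling = "numeric", betweenCoupling = "numeric",
                 stateSequence = "character", noiseSd = "numeric",
                 hrfSmoothing = "logical", seed = "integer",
                 betweenMatrices = "list"))

setValidity("SyntheticSpec", function(object) {
  if (sum(object@moduleSizes) != object@nRegions)
    return("module sizes must sum to nRegions")
  if (any(object@moduleSizes < 1L)) return("module sizes must be positive")
  if (length(object@stateSequence) != object@nFrames)
    return("stateSequence must have one label per frame")
  if (!all(object@stateSequence %in% names(object@betweenCoupling)))
    return("every state label needs an entry in betweenCoupling")
  if (object@withinCoupling < 0 || object@withinCoupling >= 1)
    return("withinCoupling must lie in [0, 1)")
  if (object@tr <= 0) return("tr must be positive (seconds)")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  for (s in unique(object@stateSequence)) {
    S <- blockCovariance(object@moduleSizes, object@withinCoupling,
                         stateBetween(object, s))
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      return(sprintf(
        "state '%s' gives a non-positive-semidefinite target covariance (min eigenvalue %.3g)",
        s, ev))
  }
  TRUE
})

# Target covariance: unit variances, `within` inside blocks, `between`
# across blocks. `between` is a scalar or a k x k matrix of per-module-pair
# couplings (k = number of modules), enabling states in which specific
# module pairs merge.
blockCovariance <- function(moduleSizes, within, between) {
  n <- sum(moduleSizes)
  k <- length(moduleSizes)
  if (is.matrix(between)) {
    stopifnot(nrow(between) == k, ncol(between) == k)
    blk <- rep(seq_len(k), moduleSizes)
    S <- between[blk, blk]
  } else {
    S <- matrix(between, n, n)
  }
  off <- 0L
  for (m in moduleSizes) {
    idx <- off + seq_len(m)
    S[idx, idx] <- within
    off <- off + m
  }
  diag(S) <- 1
  S
}

# Effective between-module coupling of a state: the per-pair matrix when one
# is supplied, otherwise the scalar from betweenCoupling.
stateBetween <- function(spec, s) {
  if (!is.null(spec@betweenMatrices[[s]])) spec@betweenMatrices[[s]]
  else spec@betweenCoupling[[s]]
}

#' Build a synthetic-data specification
#'
#' Defaults emulate a single resting-state acquisition: 375 regions in twelve
#' near-equal modules, 216 frames at TR 2.2 s, moderate modular structure
#' (within 0.5 / between 0.1), no added noise and no haemodynamic smoothing.
#'
#' @param nRegions,moduleSizes,tr,nFrames,withinCoupling,betweenCoupling,
#'   stateSequence,noiseSd,hrfSmoothing,seed see [SyntheticSpec-class].
#'   `betweenCoupling` is a named numeric vector (default a single "rest"
#'   state); `stateSequence` defaults to all-"rest".
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nRegions = 375L,
                          moduleSizes = NULL,
                          tr = 2.2,
                          nFrames = 216L,
                          withinCoupling = 0.5,
                          betweenCoupling = c(rest = 0.1),
                          stateSequence = NULL,
                          noiseSd = 0,
                          hrfSmoothing = FALSE,
                          seed = 1L,
                          betweenMatrices = list()) {
  nRegions <- as.integer(nRegions)
  if (is.null(moduleSizes)) {
    k <- min(12L, nRegions %/% 2L)
    base <- nRegions %/% k
    moduleSizes <- rep(base, k)
    moduleSizes[seq_len(nRegions - base * k)] <-
      moduleSizes[seq_len(nRegions - base * k)] + 1L
  }
  if (is.null(names(betweenCoupling)))
    names(betweenCoupling) <- paste0("state", seq_along(betweenCoupling))
  if (is.null(stateSequence))
    stateSequence <- rep(names(betweenCoupling)[1], nFrames)
  new("SyntheticSpec", nRegions = nRegions,
      moduleSizes = as.integer(moduleSizes), tr = tr,
      nFrames = as.integer(nFrames), withinCoupling = withinCoupling,
      betweenCoupling = betweenCoupling,
      stateSequence = as.character(stateSequence), noiseSd = noiseSd,
      hrfSmoothing = hrfSmoothing, seed = as.integer(seed),
      betweenMatrices = betweenMatrices)
}

#' Generate a modular BOLD-like run with ground truth
#'
#' Draws frames independently from a zero-mean Gaussian whose covariance is
#' the block matrix of the frame's state, optionally adds white noise and
#' optionally convolves each region with the canonical double-gamma kernel.
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `ts` (a [ParcellatedTimeSeries-class]) and
#'   `groundTruth` (planted partition, per-frame applied between-module
#'   coupling, state sequence).
#' @export
generateModularBold <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    X <- drawStateFrames(spec)
    if (spec@noiseSd > 0)
      X <- X + spec@noiseSd * matrix(rnorm(length(X)), nrow(X), ncol(X))
    if (spec@hrfSmoothing)
      X <- hrfSmooth(X, spec@tr)
    labels <- paste0("R", seq_len(spec@nRegions))
    ts <- ParcellatedTimeSeries(X, tr = spec@tr, regionLabels = labels,
                                runMeta = list(condition = "rest"))
    list(ts = ts, groundTruth = groundTruthOf(spec))
  })
}

drawStateFrames <- function(spec) {
  N <- spec@nRegions
  X <- matrix(0, spec@nFrames, N)
  chols <- lapply(unique(spec@stateSequence), function(s) {
    S <- blockCovariance(spec@moduleSizes, spec@withinCoupling,
                         stateBetween(spec, s))
    # tolerate tiny negative eigenvalues already vetted by the validity check
    ce <- tryCatch(chol(S), error = function(e) {
      ed <- eigen(S, symmetric = TRUE)
      chol(ed$vectors %*% diag(pmax(ed$values, 1e-10)) %*% t(ed$vectors))
    })
    ce
  })
  names(chols) <- unique(spec@stateSequence)
  Z <- matrix(rnorm(spec@nFrames * N), spec@nFrames, N)
  for (s in unique(spec@stateSequence)) {
    idx <- which(spec@stateSequence == s)
    X[idx, ] <- Z[idx, , drop = FALSE] %*% chols[[s]]
  }
  X
}

hrfSmooth <- function(X, tr) {
  h <- hrfKernel(tr)
  apply(X, 2, function(x) {
    as.numeric(stats::filter(c(rep(0, length(h) - 1), x), h,
                             method = "convolution",
                             sides = 1))[length(h) - 1 + seq_along(x)]
  })
}

groundTruthOf <- function(spec) {
  partition <- rep(seq_along(spec@moduleSizes), spec@moduleSizes)
  list(plantedPartition = partition,
       latentIntegration = unname(spec@betweenCoupling[spec@stateSequence]),
       stateSequence = spec@stateSequence)
}

#' Generate a pupil trace coupled to latent network integration
#'
#' The trace is the latent integration series delayed by `lag` seconds,
#' optionally smoothed with a centred moving average, plus Gaussian noise;
#' the result is z-scored. With `noiseSd = 0` and `smoothFrames = 1` it is an
#' exact (shifted) monotone copy of the latent series.
#'
#' @param latentIntegration per-frame between-module coupling actually
#'   applied (from a generator's ground truth).
#' @param tr frame duration in seconds.
#' @param lag non-negative delay in seconds.
#' @param noiseSd sd of additive Gaussian noise, in units of the latent
#'   series.
#' @param seed integer seed.
#' @param smoothFrames width (frames) of the moving-average smoother.
#' @return a z-scored [PupilSeries-class] at the frame rate.
#' @export
generatePupil <- function(latentIntegration, tr, lag = 0, noiseSd = 0,
                          seed = 1L, smoothFrames = 1L) {
  stopifnot(lag >= 0, smoothFrames >= 1L)
  withSeed(seed, {
    x <- as.numeric(latentIntegration)
    k <- as.integer(round(lag / tr))
    if (k > 0) x <- c(rep(x[1], k), x[seq_len(length(x) - k)])
    if (smoothFrames > 1L) {
      kern <- rep(1 / smoothFrames, smoothFrames)
      x <- as.numeric(stats::filter(x, kern, sides = 2))
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    }
    if (noiseSd > 0) x <- x + rnorm(length(x), sd = noiseSd)
    s <- stats::sd(x)
    z <- if (s > 0) (x - mean(x)) / s else x - mean(x)
    PupilSeries(z, rate = 1 / tr, zScored = TRUE)
  })
}

#' Generate a task run with load-dependent integration
#'
#' Frames falling inside a design block take the between-module coupling
#' mapped from the block's condition by `loadProfile` (an inverted-U profile
#' is simply a non-monotone map); all other frames use the spec's baseline
#' state. Blocks must not overlap and must fit within the run.
#'
#' @param spec a [SyntheticSpec-class]; its first state is the baseline.
#' @param design data.frame with columns `condition`, `onset` (s),
#'   `duration` (s). An empty design gives a pure baseline run.
#' @param loadProfile named numeric: condition -> between-module coupling.
#'   Conditions absent from the profile (e.g. "instruction") use baseline.
#' @return list with `ts`, `groundTruth` (including the design) as in
#'   [generateModularBold()].
#' @export
generateTaskRun <- function(spec, design, loadProfile) {
  stopifnot(is(spec, "SyntheticSpec"))
  design <- as.data.frame(design)
  if (nrow(design) > 0) {
    stopifnot(all(c("condition", "onset", "duration") %in% names(design)))
    d <- design[order(design$onset), , drop = FALSE]
    ends <- d$onset + d$duration
    if (any(d$onset[-1] < ends[-nrow(d)] - 1e-9))
      stop("design blocks overlap")
    if (max(ends) > spec@nFrames * spec@tr + 1e-9)
      stop("design blocks extend beyond the run")
  }
  baseline <- names(spec@betweenCoupling)[1]
  states <- rep(baseline, spec@nFrames)
  centers <- (seq_len(spec@nFrames) - 0.5) * spec@tr
  for (b in seq_len(nrow(design))) {
    inBlock <- centers >= design$onset[b] &
      centers < design$onset[b] + design$duration[b]
    cond <- as.character(design$condition[b])
    if (cond %in% names(loadProfile)) states[inBlock] <- cond
  }
  bc <- c(spec@betweenCoupling[baseline], loadProfile)
  bc <- bc[!duplicated(names(bc))]
  runSpec <- new("SyntheticSpec", nRegions = spec@nRegions,
                 moduleSizes = spec@moduleSizes, tr = spec@tr,
                 nFrames = spec@nFrames, withinCoupling = spec@withinCoupling,
                 betweenCoupling = bc, stateSequence = states,
                 noiseSd = spec@noiseSd, hrfSmoothing = spec@hrfSmoothing,
                 seed = spec@seed)
  out <- generateModularBold(runSpec)
  out$ts@runMeta$condition <- "task"
  out$groundTruth$design <- design
  out
}

#' Generate a double-blind crossover cohort
#'
#' Each subject contributes four resting runs (pre/post x drug/placebo). A
#' Gaussian random intercept per subject perturbs the between-module
#' coupling, and the post-drug run's coupling is additionally shifted by
#' `drugIntegrationShift` (negative values segregate the network). Couplings
#' that would fall below zero are truncated at zero with a warning.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param spec baseline run recipe; its first state supplies the baseline
#'   between-module coupling.
#' @param drugIntegrationShift signed shift applied post-drug.
#' @param seed integer master seed.
#' @param subjectSd sd of the per-subject random intercept on coupling.
#' @return list with `runs` (list of [ParcellatedTimeSeries-class]),
#'   `groundTruth` (per-run), and `meta` (tidy data.frame: subject, session,
#'   treatment, applied coupling, run seed).
#' @export
generateCrossoverCohort <- function(nSubjects, spec, drugIntegrationShift = 0,
                                    seed = 1L, subjectSd = 0.02) {
  stopifnot(nSubjects >= 2, is(spec, "SyntheticSpec"))
  baseline <- spec@betweenCoupling[[1]]
  intercepts <- withSeed(deriveSeed(seed, "subject-intercepts"),
                         rnorm(nSubjects, sd = subjectSd))
  grid <- expand.grid(treatment = c("placebo", "drug"),
                      session = c("pre", "post"),
                      stringsAsFactors = FALSE)
  runs <- list(); gts <- list(); meta <- NULL
  for (s in seq_len(nSubjects)) {
    for (g in seq_len(nrow(grid))) {
      shift <- if (grid$treatment[g] == "drug" && grid$session[g] == "post")
        drugIntegrationShift else 0
      bc <- baseline + intercepts[s] + shift
      if (bc < 0) {
        warning("between-module coupling truncated at 0 for subject ", s)
        bc <- 0
      }
      runSeed <- deriveSeed(seed, sprintf("run-%d-%s-%s", s,
                                          grid$session[g], grid$treatment[g]))
      runSpec <- new("SyntheticSpec", nRegions = spec@nRegions,
                     moduleSizes = spec@moduleSizes, tr = spec@tr,
                     nFrames = spec@nFrames,
                     withinCoupling = spec@withinCoupling,
                     betweenCoupling = c(rest = bc),
                     stateSequence = rep("rest", spec@nFrames),
                     noiseSd = spec@noiseSd,
                     hrfSmoothing = spec@hrfSmoothing,
                     seed = runSeed)
      out <- generateModularBold(runSpec)
      id <- sprintf("sub%02d_%s_%s", s, grid$session[g], grid$treatment[g])
      out$ts@runMeta <- list(subject = sprintf("sub%02d", s),
                             session = grid$session[g],
                             treatment = grid$treatment[g])
      runs[[id]] <- out$ts
      gts[[id]] <- out$groundTruth
      meta <- rbind(meta, data.frame(run = id, subject = sprintf("sub%02d", s),
                                     session = grid$session[g],
                                     treatment = grid$treatment[g],
                                     betweenCoupling = bc, seed = runSeed,
                                     stringsAsFactors = FALSE))
    }
  }
  list(runs = runs, groundTruth = gts, meta = meta)
}
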