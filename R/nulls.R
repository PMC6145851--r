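# Stationary covariance of the companion-form VAR via the doubling
# iteration S <- S + A S A' with A <- A A (converges when the spectral
# radius is below 1).
stationaryCov <- function(Acomp, Qcomp, iter = 60L) {
  S <- Qcomp; A <- Acomp
  for (i in seq_len(iter)) {
    S <- S + A %*% S %*% t(A)
    A <- A %*% A
    if (max(abs(A)) < 1e-300) break
  }
  S
}

companionMatrix <- function(coefs) {
  d <- dim(coefs)[1]; p <- dim(coefs)[3]
  A <- matrix(0, d * p, d * p)
  for (l in seq_len(p)) A[seq_len(d), (l - 1) * d + seq_len(d)] <- coefs[, , l]
  if (p > 1)
    A[d + seq_len(d * (p - 1)), seq_len(d * (p - 1))] <- diag(d * (p - 1))
  A
}

#' Fit a stationary VAR surrogate model
#'
#' Least-squares VAR fit on (per-run demeaned, concatenated) parcellated
#' time series. The model order 6 captures the temporal signature of the
#' haemodynamic response at typical TRs. Surrogates simulated from the model
#' are linearly transformed so their stationary covariance equals the
#' empirical mean covariance of the training data, reconciling coefficient
#' fitting with covariance matching. When the region count exceeds
#' `subspaceDim`, fitting is performed on the top principal subspace and
#' projected back (a message reports this loudly), with per-region white
#' noise restoring the variance lost to truncation.
#'
#' @param tsList a [ParcellatedTimeSeries-class] or list of them (same
#'   regions).
#' @param order VAR order p (default 6); `order = 0` yields a pure
#'   covariance-matched white-noise model.
#' @param subspaceDim maximum fitting dimension (default 50).
#' @return a [VarModel-class].
#' @export
fitVar <- function(tsList, order = 6L, subspaceDim = 50L) {
  if (is(tsList, "ParcellatedTimeSeries")) tsList <- list(tsList)
  stopifnot(length(tsList) >= 1L)
  order <- as.integer(order)
  labels <- regionLabels(tsList[[1]])
  tr <- trSeconds(tsList[[1]])
  Xs <- lapply(tsList, function(ts) {
    X <- tsData(ts)
    sweep(X, 2, colMeans(X))
  })
  N <- ncol(Xs[[1]])
  totalRows <- sum(vapply(Xs, nrow, numeric(1)) - order)
  C <- Reduce(`+`, lapply(Xs, function(X) crossprod(X))) /
    sum(vapply(Xs, nrow, numeric(1)))
  grandMean <- Reduce(`+`, lapply(tsList, function(ts) colMeans(tsData(ts)))) /
    length(tsList)

  d <- min(N, as.integer(subspaceDim))
  if (d < N) {
    message("fitVar: reducing ", N, " regions to the top ", d,
            " principal components for VAR fitting; surrogates are projected back")
    ed <- eigen(C, symmetric = TRUE)
    V <- ed$vectors[, seq_len(d), drop = FALSE]
  } else {
    V <- diag(N)
  }
  if (order > 0 && totalRows < order * d + 10L)
    stop("too few frames (", totalRows, ") for a VAR(", order, ") on ", d,
         " dimensions; reduce `order` or `subspaceDim`")
  Zs <- lapply(Xs, function(X) X %*% V)
  Csub <- crossprod(V, C %*% V)

  if (order == 0L) {
    coefs <- array(0, c(d, d, 1L))[, , 0L, drop = FALSE]
    dim(coefs) <- c(d, d, 0L)
    Q <- Csub
    Simp <- Csub
  } else {
    # stacked lagged regression Y = X B across runs
    XY <- lapply(Zs, function(Z) {
      Tn <- nrow(Z)
      Y <- Z[(order + 1):Tn, , drop = FALSE]
      Xl <- do.call(cbind, lapply(seq_len(order), function(l)
        Z[(order + 1 - l):(Tn - l), , drop = FALSE]))
      list(Y = Y, X = Xl)
    })
    Xall <- do.call(rbind, lapply(XY, `[[`, "X"))
    Yall <- do.call(rbind, lapply(XY, `[[`, "Y"))
    Bhat <- tryCatch(solve(crossprod(Xall), crossprod(Xall, Yall)),
                     error = function(e)
                       stop("VAR design is singular; reduce `order` or `subspaceDim`"))
    res <- Yall - Xall %*% Bhat
    Q <- crossprod(res) / nrow(res)
    coefs <- array(0, c(d, d, order))
    for (l in seq_len(order))
      coefs[, , l] <- t(Bhat[(l - 1) * d + seq_len(d), , drop = FALSE])
    Acomp <- companionMatrix(coefs)
    sr <- max(Mod(eigen(Acomp, only.values = TRUE)$values))
    if (sr >= 1)
      stop(sprintf("fitted VAR is unstable (spectral radius %.4f)", sr))
    Qcomp <- matrix(0, d * order, d * order)
    Qcomp[seq_len(d), seq_len(d)] <- Q
    Simp <- stationaryCov(Acomp, Qcomp)[seq_len(d), seq_len(d)]
  }
  # transform so simulated stationary covariance matches the empirical one
  M <- t(chol(Csub + diag(1e-12, d))) %*%
    solve(t(chol(Simp + diag(1e-12, d))))
  compVar <- pmax(diag(C) - diag(V %*% Csub %*% t(V)), 0)
  new("VarModel", order = order, coefs = coefs,
      innovChol = chol(Q + diag(1e-12, d)), transform = M, projection = V,
      complementSd = sqrt(compVar), mean = grandMean, empCov = C,
      regionLabels = labels, tr = tr)
}

#' Simulate stationary surrogate time series from a VAR model
#'
#' Gaussian-innovation simulation with burn-in discarded, covariance-matching
#' transform applied, principal-subspace projection reversed, and (by
#' default) the same 0.01-0.125 Hz band-pass as the analysis path, so
#' surrogates traverse the identical preprocessing as real data. Set
#' `bandpass = NULL` to obtain raw stationary draws.
#'
#' @param model a [VarModel-class].
#' @param nFrames frames per surrogate.
#' @param nSurrogates number of surrogates (2500 gives stable tail
#'   estimates; reduce for calibration studies).
#' @param seed integer seed.
#' @param bandpass c(low, high) in Hz, or NULL to skip filtering.
#' @param burn burn-in frames discarded.
#' @return frames x regions x surrogates array (region labels in dimnames).
#' @export
simulateVar <- function(model, nFrames, nSurrogates = 2500L, seed = 1L,
                        bandpass = c(0.01, 0.125), burn = 200L) {
  stopifnot(is(model, "VarModel"))
  d <- ncol(model@projection); N <- nrow(model@projection)
  p <- model@order
  Ttot <- nFrames + (if (p > 0) burn else 0L)
  S <- as.integer(nSurrogates)
  out <- withSeed(seed, {
    # pre-draw all innovations, then run the recursion in compiled code
    E <- array(rnorm(Ttot * d * S), c(Ttot, d, S))
    Em <- matrix(E, Ttot, d * S)
    # innovation covariance: x_t innovation = L e_t with L = t(innovChol)
    for (s in seq_len(S)) {
      idx <- (s - 1L) * d + seq_len(d)
      Em[, idx] <- Em[, idx, drop = FALSE] %*% model@innovChol
    }
    if (p == 0L) {
      array(Em, c(Ttot, d, S))
    } else {
      cpp_var_recursion(array(Em, c(Ttot, d, S)), model@coefs, d, p, S,
                        Ttot, as.integer(burn))
    }
  })
  # covariance-matching transform + projection back to region space,
  # vectorised over surrogates
  MV <- model@projection %*% model@transform  # N x d
  flatd <- matrix(aperm(out, c(1, 3, 2)), nFrames * S, d)
  flatN <- flatd %*% t(MV)
  if (any(model@complementSd > 0)) {
    cn <- withSeed(deriveSeed(seed, "complement"),
                   matrix(rnorm(nFrames * S * N), nFrames * S, N))
    flatN <- flatN + sweep(cn, 2, model@complementSd, "*")
  }
  res <- aperm(array(flatN, c(nFrames, S, N)), c(1, 3, 2))
  dimnames(res) <- list(NULL, model@regionLabels, NULL)
  if (!is.null(bandpass)) {
    fs <- 1 / model@tr
    co <- butterCoefs("pass", bandpass, fs, 2)
    flat <- matrix(res, nFrames, N * nSurrogates)
    flat <- filtfiltMat(co$b, co$a, flat)
    res <- array(flat, dim(res), dimnames = dimnames(res))
  }
  res
}

#' Mean participation series under a fixed partition
#'
#' Fast path used when scoring many surrogates: the per-window mean
#' participation coefficient of the MTD windows of a run, computed under a
#' single fixed module partition (e.g. the consensus partition of the
#' observed run's time-averaged graph). Identical to running
#' [mtdCoupling()], then [participationCoef()] per window with that
#' partition, then averaging over regions.
#'
#' @param x a [ParcellatedTimeSeries-class] or a plain frames x regions
#'   matrix.
#' @param membership fixed module labels (one per region).
#' @param w MTD window length in frames.
#' @return per-window mean participation coefficient.
#' @export
meanParticipationSeries <- function(x, membership, w = 15L) {
  X <- if (is(x, "ParcellatedTimeSeries")) tsData(x) else as.matrix(x)
  D <- diff(X)
  sigma <- apply(D, 2, popSd)
  if (any(sigma == 0)) stop("constant derivative in region ",
                            which(sigma == 0)[1])
  D <- sweep(D, 2, sigma, "/")
  cpp_mean_participation_series(D, as.integer(w),
                                as.integer(as.integer(factor(membership))))
}

#' Mean participation series for a whole surrogate set
#'
#' Applies [meanParticipationSeries()] to every surrogate of a
#' [simulateVar()] array in one compiled pass.
#'
#' @param surr frames x regions x surrogates array.
#' @param membership fixed module labels.
#' @param w MTD window length.
#' @return windows x surrogates matrix of per-window mean participation.
#' @export
surrogateMeanParticipation <- function(surr, membership, w = 15L) {
  stopifnot(length(dim(surr)) == 3L)
  Tn <- dim(surr)[1]; N <- dim(surr)[2]; S <- dim(surr)[3]
  flat <- matrix(surr, Tn, N * S)
  D <- diff(flat)
  sds <- sqrt(colMeans(D^2) - colMeans(D)^2)
  if (any(sds == 0)) stop("constant derivative in a surrogate")
  D <- sweep(D, 2, sds, "/")
  cpp_mean_participation_batch(array(D, c(Tn - 1L, N, S)), as.integer(w),
                               as.integer(as.integer(factor(membership))),
                               Tn - 1L, N, S)
}

#' Kurtosis test of network dynamism against a surrogate null
#'
#' Tests whether the observed mean-participation series fluctuates more than
#' stationary linear surrogates: the statistic is the Pearson kurtosis
#' (plain fourth standardised moment, not excess) of either the
#' window-to-window difference of the series (`variant = "diff"`, the
#' preregistered form) or of the series itself (`variant = "level"`). The
#' observation is called significant when it exceeds the 95th percentile of
#' the surrogate statistics (one-sided by construction).
#'
#' @param observed per-window mean participation of the observed run.
#' @param surrogates matrix (windows x surrogates) of surrogate series, or a
#'   numeric vector of precomputed surrogate statistics.
#' @param variant `"diff"` (default) or `"level"`.
#' @param prob percentile defining the decision threshold.
#' @return list with `statistic`, `nullStats`, `threshold`, `significant`,
#'   `percentile` (rank of the observation in the null), `variant`.
#' @export
kurtosisTest <- function(observed, surrogates, variant = c("diff", "level"),
                         prob = 0.95) {
  variant <- match.arg(variant)
  stat <- function(x) {
    y <- if (variant == "diff") diff(x) else x
    pearsonKurtosis(y)
  }
  obs <- stat(observed)
  nullStats <- if (is.matrix(surrogates)) {
    if (ncol(surrogates) < 2L) stop("need at least 2 surrogates")
    apply(surrogates, 2, stat)
  } else {
    if (length(surrogates) < 2L) stop("need at least 2 surrogates")
    as.numeric(surrogates)
  }
  thr <- as.numeric(quantile(nullStats, prob, type = 7))
  list(statistic = obs, nullStats = nullStats, threshold = thr,
       significant = obs > thr, percentile = mean(nullStats < obs),
       variant = variant)
}
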