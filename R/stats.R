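#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up FDR procedure at level `q`; returns the rejection mask, the
#' adjusted p-values and the largest raw p-value rejected (NA when nothing
#' is rejected). A thin wrapper around [stats::p.adjust()] so decisions and
#' adjusted values stay consistent.
#'
#' @param pvals p-values in \[0, 1\] (NAs are never rejected).
#' @param q target FDR.
#' @return list with `reject` (logical), `padj`, `threshold`.
#' @export
fdrBh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L)
    return(list(reject = logical(0), padj = numeric(0), threshold = NA_real_))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  padj <- rep(NA_real_, length(pvals))
  padj[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  reject <- !is.na(padj) & padj <= q
  thr <- if (any(reject)) max(pvals[reject]) else NA_real_
  list(reject = reject, padj = padj, threshold = thr)
}

#' Per-bin 2x2 within-subject (crossover) ANOVA
#'
#' For every histogram bin, a 2 (session: pre/post) x 2 (treatment:
#' drug/placebo) fully within-subject ANOVA of occupancy, testing the
#' session x treatment interaction - the crossover drug effect. The F
#' statistic is computed from the classical sums-of-squares decomposition
#' (interaction SS against its subject-interaction error term, df 1 and
#' n - 1) and equals the squared paired t of the per-subject interaction
#' contrast. P-values are FDR-corrected across bins.
#'
#' @param occ observations x bins matrix of occupancy (one row per
#'   subject-session cell).
#' @param subject,session,treatment factors describing each row; every
#'   subject needs all four cells exactly once.
#' @param q FDR level.
#' @return data.frame with per-bin F, p, padj, reject, and the mean
#'   interaction contrast `delta` ((post-pre)_drug - (post-pre)_placebo).
#' @export
binAnova2x2 <- function(occ, subject, session, treatment, q = 0.05) {
  occ <- as.matrix(occ)
  subject <- factor(subject); session <- factor(session)
  treatment <- factor(treatment)
  stopifnot(nlevels(session) == 2L, nlevels(treatment) == 2L)
  tab <- table(subject, session, treatment)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[apply(tab != 1L, 1, any)]
    stop("incomplete 2x2 design for subject(s): ", paste(bad, collapse = ", "))
  }
  n <- nlevels(subject)
  # reshape to subject x cell arrays per bin
  key <- interaction(session, treatment)
  cells <- levels(key)
  Y <- array(0, c(n, 4L, ncol(occ)))
  for (ci in seq_along(cells)) {
    rows <- which(key == cells[ci])
    Y[as.integer(subject[rows]), ci, ] <- occ[rows, ]
  }
  sesOf <- as.integer(sub("\\..*", "", cells) == levels(session)[2]) + 1L
  trtOf <- as.integer(sub(".*\\.", "", cells) == levels(treatment)[2]) + 1L
  # sums-of-squares route, vectorised over bins
  grand <- apply(Y, 3, mean)
  cellM <- apply(Y, c(2, 3), mean)                       # 4 x bins
  sesM <- rbind(colMeans(cellM[sesOf == 1L, , drop = FALSE]),
                colMeans(cellM[sesOf == 2L, , drop = FALSE]))
  trtM <- rbind(colMeans(cellM[trtOf == 1L, , drop = FALSE]),
                colMeans(cellM[trtOf == 2L, , drop = FALSE]))
  inter <- sweep(cellM, 2, grand, "+") -
    sesM[sesOf, , drop = FALSE] - trtM[trtOf, , drop = FALSE]
  ssAB <- n * colSums(inter^2)
  # error: subject x session x treatment residual
  subjM <- apply(Y, c(1, 3), mean)                       # n x bins
  subjSes <- array(0, c(n, 2L, dim(Y)[3]))
  subjTrt <- array(0, c(n, 2L, dim(Y)[3]))
  for (l in 1:2) {
    subjSes[, l, ] <- apply(Y[, sesOf == l, , drop = FALSE], c(1, 3), mean)
    subjTrt[, l, ] <- apply(Y[, trtOf == l, , drop = FALSE], c(1, 3), mean)
  }
  resid <- Y
  for (ci in 1:4) {
    resid[, ci, ] <- Y[, ci, ] -
      subjSes[, sesOf[ci], ] - subjTrt[, trtOf[ci], ] + subjM -
      matrix(cellM[ci, ], n, dim(Y)[3], byrow = TRUE) +
      matrix(sesM[sesOf[ci], ], n, dim(Y)[3], byrow = TRUE) +
      matrix(trtM[trtOf[ci], ], n, dim(Y)[3], byrow = TRUE) -
      matrix(grand, n, dim(Y)[3], byrow = TRUE)
  }
  ssErr <- apply(resid^2, 3, sum)
  Fv <- ifelse(ssErr > 0, ssAB / (ssErr / (n - 1)), 0)
  p <- pf(Fv, 1, n - 1, lower.tail = FALSE)
  p[ssErr == 0 & ssAB == 0] <- 1
  fdr <- fdrBh(p, q)
  # per-subject interaction contrast (post - pre)_drug - (post - pre)_placebo
  cid <- function(s, t) which(sesOf == s & trtOf == t)
  delta <- colMeans(Y[, cid(2, 2), ] - Y[, cid(1, 2), ] -
                      Y[, cid(2, 1), ] + Y[, cid(1, 1), ])
  data.frame(bin = seq_len(ncol(occ)), F = Fv, p = p, padj = fdr$padj,
             reject = fdr$reject, delta = delta)
}

#' Pupil-topology correlation with mixed-effects group inference
#'
#' Per subject, the z-scored pupil trace is convolved with the canonical
#' double-gamma kernel, averaged over the frames of each MTD window, and
#' Spearman-correlated with each cartographic-profile bin's occupancy
#' series. Group inference fits a linear mixed model on the Fisher-z
#' transformed correlations, `z ~ 0 + bin + (1 | subject)`, and FDR-corrects
#' the per-bin Wald tests (Satterthwaite df).
#'
#' @param pupilWindows list (per subject) of per-window pupil values, e.g.
#'   from [windowAverage()] after [preprocessPupil()] and kernel
#'   convolution; use [convolveHrf()] to apply the kernel.
#' @param binSeries list (per subject) of windows x bins occupancy matrices
#'   from [windowOccupancySeries()] (same bin geometry for all subjects).
#' @param q FDR level.
#' @return list with `rho` (subjects x bins), `perBin` data.frame (estimate
#'   on the Fisher-z scale, t, p, padj, reject).
#' @export
pupilTopologyCorrelation <- function(pupilWindows, binSeries, q = 0.05) {
  stopifnot(length(pupilWindows) == length(binSeries),
            length(pupilWindows) >= 2L)
  nbins <- ncol(binSeries[[1]])
  rho <- matrix(NA_real_, length(pupilWindows), nbins)
  for (s in seq_along(pupilWindows)) {
    pv <- pupilWindows[[s]]
    bs <- binSeries[[s]]
    stopifnot(length(pv) == nrow(bs), ncol(bs) == nbins)
    keep <- apply(bs, 2, function(col) stats::sd(col) > 0)
    if (stats::sd(pv) > 0 && any(keep))
      rho[s, keep] <- suppressWarnings(
        cor(pv, bs[, keep, drop = FALSE], method = "spearman"))
  }
  z <- atanh(pmax(pmin(rho, 0.999999), -0.999999))
  df <- data.frame(z = as.numeric(z),
                   bin = factor(rep(seq_len(nbins), each = nrow(z))),
                   subject = factor(rep(seq_len(nrow(z)), times = nbins)))
  df <- df[is.finite(df$z), , drop = FALSE]
  usedBins <- levels(droplevels(df$bin))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(z ~ 0 + bin + (1 | subject), data = droplevels(df))))
  sm <- coef(summary(fit))
  est <- p <- tval <- rep(NA_real_, nbins)
  idx <- as.integer(usedBins)
  est[idx] <- sm[, "Estimate"]
  tval[idx] <- sm[, "t value"]
  p[idx] <- sm[, "Pr(>|t|)"]
  fdr <- fdrBh(p, q)
  list(rho = rho,
       perBin = data.frame(bin = seq_len(nbins), estimate = est, t = tval,
                           p = p, padj = fdr$padj, reject = fdr$reject))
}

#' Convolve a frame-rate covariate with the double-gamma kernel
#'
#' @param x per-frame numeric vector.
#' @param tr frame duration in seconds.
#' @return the convolved series, same length (causal kernel, zero-padded
#'   history).
#' @export
convolveHrf <- function(x, tr) {
  h <- hrfKernel(tr)
  as.numeric(stats::filter(c(rep(0, length(h) - 1), x), h,
                           method = "convolution",
                           sides = 1))[length(h) - 1 + seq_along(x)]
}

# Build the windows x k task design matrix from a block design.
taskDesignMatrix <- function(design, tr, nFrames, w, nWin, convolve = TRUE,
                             windowOffset = 0L) {
  conds <- unique(as.character(design$condition))
  centers <- (seq_len(nFrames) - 0.5) * tr
  cols <- lapply(conds, function(cn) {
    box <- rep(0, nFrames)
    for (b in which(design$condition == cn)) {
      box[centers >= design$onset[b] &
            centers < design$onset[b] + design$duration[b]] <- 1
    }
    if (convolve) convolveHrf(box, tr) else box
  })
  X <- do.call(cbind, cols)
  colnames(X) <- conds
  Xw <- windowAverage(X, w = w, stride = 1L, n = nWin)
  if (windowOffset != 0L) {
    Xw <- rbind(matrix(0, max(0, windowOffset), ncol(X)),
                Xw)[seq_len(nWin) + max(0, -windowOffset), , drop = FALSE]
  }
  colnames(Xw) <- conds
  Xw
}

#' Task GLM on windowed topology with main- and load-effect contrasts
#'
#' Ordinary least squares of each unit's (region's or bin's) windowed
#' topology series on the task design: condition boxcars optionally
#' convolved with the double-gamma kernel, averaged over each MTD window,
#' plus an intercept and any nuisance regressors. Two F contrasts are
#' formed on the 0/1/2/3-back betas: the main effect (mean of 1-3-back
#' versus 0-back) and the load effect (linear increase across the four
#' loads). Single-degree contrasts are tested via their t statistic
#' (F = t^2); p-values are FDR-corrected across units.
#'
#' @param Y windows x units response matrix (e.g. `participation(topo)`).
#' @param design data.frame with `condition` (containing "0back", "1back",
#'   "2back", "3back", possibly "instruction"/"rest"), `onset` (s),
#'   `duration` (s).
#' @param tr repetition time (s).
#' @param nFrames frames in the run.
#' @param w MTD window length used to produce `Y`.
#' @param nuisance optional windows x q matrix of nuisance regressors.
#' @param convolve convolve boxcars with the double-gamma kernel.
#' @param windowOffset integer shift (windows) between design and topology.
#' @param q FDR level.
#' @return list with `betas`, and data.frames `main` and `load` (F, p,
#'   padj, reject per unit).
#' @export
taskGlm <- function(Y, design, tr, nFrames, w = 15L, nuisance = NULL,
                    convolve = TRUE, windowOffset = 0L, q = 0.05) {
  Y <- as.matrix(Y)
  design <- as.data.frame(design)
  backs <- c("0back", "1back", "2back", "3back")
  if (!any(as.character(design$condition) %in% backs))
    stop("design contains no task (n-back) blocks")
  Xt <- taskDesignMatrix(design, tr, nFrames, w, nrow(Y), convolve,
                         windowOffset)
  X <- cbind(`(Intercept)` = 1, Xt)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    dropped <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  rownames(B) <- colnames(X)
  E <- Y - X %*% B
  dfRes <- nrow(Y) - ncol(X)
  s2 <- colSums(E^2) / dfRes
  contrastTest <- function(cvec) {
    cv <- numeric(ncol(X)); names(cv) <- colnames(X)
    cv[names(cvec)] <- cvec
    num <- as.numeric(cv %*% B)
    den <- sqrt(as.numeric(t(cv) %*% XtXinv %*% cv) * s2)
    tstat <- ifelse(den > 0, num / den, 0)
    Fv <- tstat^2
    p <- pf(Fv, 1, dfRes, lower.tail = FALSE)
    fdr <- fdrBh(p, q)
    data.frame(unit = seq_len(ncol(Y)), estimate = num, F = Fv, p = p,
               padj = fdr$padj, reject = fdr$reject)
  }
  present <- intersect(backs, colnames(X))
  if (!setequal(present, backs))
    stop("design must include all of 0back..3back; missing: ",
         paste(setdiff(backs, present), collapse = ", "))
  main <- contrastTest(c(`0back` = -1, `1back` = 1 / 3, `2back` = 1 / 3,
                         `3back` = 1 / 3))
  load <- contrastTest(c(`0back` = -3, `1back` = -1, `2back` = 1,
                         `3back` = 3) / sqrt(20))
  list(betas = B, main = main, load = load, df = dfRes)
}

#' Permutation test for a Pearson correlation
#'
#' Two-sided: `p = (1 + #{|r_perm| >= |r_obs|}) / (nPerm + 1)` over seeded
#' random permutations of `y`.
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant).
#' @param nPerm number of permutations (default 5000).
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
permutationCorrTest <- function(x, y, nPerm = 5000L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r <- cor(x, y)
  withSeed(seed, {
    perm <- vapply(seq_len(nPerm), function(i) cor(x, sample(y)), numeric(1))
    p <- (1 + sum(abs(perm) >= abs(r) - 1e-12)) / (nPerm + 1)
    list(r = r, p = p)
  })
}

#' Bootstrap percentile confidence interval for a Pearson correlation
#'
#' @param x,y equal-length numeric vectors (n >= 5).
#' @param nBoot bootstrap resamples (default 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `r`, `ci` (length 2), `boot` (resampled correlations).
#' @export
bootstrapCorrCi <- function(x, y, nBoot = 1000L, level = 0.95, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  n <- length(x)
  withSeed(seed, {
    boot <- vapply(seq_len(nBoot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(x[idx], y[idx]))
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    alpha <- (1 - level) / 2
    ci <- as.numeric(quantile(boot, c(alpha, 1 - alpha), type = 7))
    list(r = cor(x, y), ci = ci, boot = boot)
  })
}

#' Dunn and Clark z test comparing two correlations
#'
#' Fisher-z based comparison of correlations measured on two datasets. With
#' `rCross = 0` (the default) it reduces to the independent-samples z test;
#' a nonzero `rCross` models the dependency between the two correlation
#' estimates (requires `n1 == n2`) by reducing the variance of the
#' difference accordingly.
#'
#' @param r1,r2 the two correlations (|r| < 1).
#' @param n1,n2 their sample sizes (>= 4).
#' @param rCross assumed correlation between the two estimates.
#' @return list with `z` and two-sided `p`.
#' @export
dunnClarkZ <- function(r1, r2, n1, n2, rCross = 0) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("degenerate correlation (|r| = 1)")
  stopifnot(n1 >= 4L, n2 >= 4L)
  if (rCross != 0 && n1 != n2)
    stop("dependency correction requires equal sample sizes")
  v <- 1 / (n1 - 3) + 1 / (n2 - 3) -
    2 * rCross * sqrt(1 / (n1 - 3)) * sqrt(1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
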