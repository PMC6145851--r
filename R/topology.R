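#' Module-degree z-score (within-module connectivity, W)
#'
#' For each region, the strength of its positive connections to other
#' members of its own module, z-scored within that module (population sd):
#' `W_i = (kappa_i - mean(kappa_module)) / sd(kappa_module)`. Modules whose
#' members all have identical within-module strength (sd 0) score 0.
#' Positive weights only are used, consistent with the participation
#' coefficient; set `weights = "signed"` to keep negative weights in kappa.
#'
#' @param W symmetric signed weight matrix (diagonal ignored).
#' @param membership integer module labels.
#' @param weights `"positive"` (default) or `"signed"`.
#' @return per-region z-scores.
#' @export
moduleDegreeZscore <- function(W, membership, weights = c("positive", "signed")) {
  weights <- match.arg(weights)
  W <- as.matrix(W); diag(W) <- 0
  if (weights == "positive") W <- pmax(W, 0)
  m <- as.integer(factor(membership))
  n <- nrow(W)
  kap <- vapply(seq_len(n), function(i) sum(W[i, m == m[i]]), numeric(1))
  out <- numeric(n)
  for (s in unique(m)) {
    idx <- m == s
    mu <- mean(kap[idx]); sdk <- popSd(kap[idx])
    out[idx] <- if (sdk > 0) (kap[idx] - mu) / sdk else 0
  }
  out
}

#' Participation coefficient (between-module connectivity, B)
#'
#' `B_i = 1 - sum_s (kappa_is / kappa_i)^2` over the strengths of the
#' positive connections of region i to each module s; `kappa_i` is its total
#' positive strength. B is 0 when all positive links stay within the
#' region's own module, approaches `1 - 1/n_M` when links spread uniformly
#' over the `n_M` modules, and is defined as 0 for isolated regions.
#'
#' @param W symmetric signed weight matrix (diagonal ignored).
#' @param membership integer module labels.
#' @return per-region participation coefficients in \[0, 1\].
#' @export
participationCoef <- function(W, membership) {
  W <- as.matrix(W); diag(W) <- 0
  m <- as.integer(factor(membership))
  res <- cpp_topology(W, m)
  res$B
}

#' Per-window cartography from a tensor and its partitions
#'
#' Computes the participation coefficient and module-degree z-score for
#' every region in every window, using each window's own partition.
#'
#' @param tensor an [MTDTensor-class].
#' @param parts the matching [WindowPartitionSet-class].
#' @return a [TopologySeries-class].
#' @export
computeTopology <- function(tensor, parts) {
  stopifnot(is(tensor, "MTDTensor"), is(parts, "WindowPartitionSet"),
            nWindows(tensor) == nWindows(parts))
  res <- cpp_topology_batch(tensor@coupling,
                            matrix(as.integer(parts@assignments),
                                   nrow(parts@assignments)))
  B <- res$B; Wz <- res$W
  new("TopologySeries", B = B, W = Wz, meanB = rowMeans(B),
      regionLabels = regionLabels(tensor))
}

#' Cartographic profile: joint (B, W) occupancy histogram
#'
#' Pools all region x window samples of the participation coefficient and
#' module-degree z-score into a fixed-geometry 2-D histogram of occupancy
#' proportions. W values outside `wRange` are clipped into the edge bins and
#' counted; B is bounded in \[0, 1\] by construction.
#'
#' @param topo a [TopologySeries-class].
#' @param nB,nW number of bins along B and W.
#' @param bRange,wRange histogram ranges.
#' @return a [CartographicProfile-class].
#' @export
cartographicProfile <- function(topo, nB = 100L, nW = 100L,
                                bRange = c(0, 1), wRange = c(-5, 5)) {
  stopifnot(is(topo, "TopologySeries"))
  b <- as.numeric(topo@B); w <- as.numeric(topo@W)
  if (length(b) == 0) stop("empty topology series")
  bEdges <- seq(bRange[1], bRange[2], length.out = nB + 1L)
  wEdges <- seq(wRange[1], wRange[2], length.out = nW + 1L)
  nClipped <- sum(w < wRange[1] | w > wRange[2]) +
    sum(b < bRange[1] | b > bRange[2])
  bi <- pmin(pmax(findInterval(b, bEdges, rightmost.closed = TRUE), 1L), nB)
  wi <- pmin(pmax(findInterval(w, wEdges, rightmost.closed = TRUE), 1L), nW)
  occ <- matrix(tabulate(bi + (wi - 1L) * nB, nbins = nB * nW) / length(b),
                nB, nW)
  new("CartographicProfile", occupancy = occ, bEdges = bEdges,
      wEdges = wEdges, nClipped = as.integer(nClipped))
}

#' Per-window bin-occupancy series
#'
#' For each temporal window, the histogram of that window's regional (B, W)
#' samples over the same fixed bin geometry as [cartographicProfile()];
#' the rows are per-window occupancy proportions. Used to correlate bin
#' occupancy with frame-locked covariates such as pupil diameter.
#'
#' @inheritParams cartographicProfile
#' @return windows x (nB*nW) matrix; columns ordered B-fastest, with
#'   attributes `bEdges`, `wEdges`, `binB`, `binW` (bin centre coordinates).
#' @export
windowOccupancySeries <- function(topo, nB = 10L, nW = 10L,
                                  bRange = c(0, 1), wRange = c(-5, 5)) {
  stopifnot(is(topo, "TopologySeries"))
  bEdges <- seq(bRange[1], bRange[2], length.out = nB + 1L)
  wEdges <- seq(wRange[1], wRange[2], length.out = nW + 1L)
  nw <- nrow(topo@B); N <- ncol(topo@B)
  out <- matrix(0, nw, nB * nW)
  for (k in seq_len(nw)) {
    bi <- pmin(pmax(findInterval(topo@B[k, ], bEdges,
                                 rightmost.closed = TRUE), 1L), nB)
    wi <- pmin(pmax(findInterval(topo@W[k, ], wEdges,
                                 rightmost.closed = TRUE), 1L), nW)
    idx <- bi + (wi - 1L) * nB
    tab <- tabulate(idx, nbins = nB * nW)
    out[k, ] <- tab / N
  }
  ctrB <- (bEdges[-1] + bEdges[-(nB + 1)]) / 2
  ctrW <- (wEdges[-1] + wEdges[-(nW + 1)]) / 2
  attr(out, "bEdges") <- bEdges; attr(out, "wEdges") <- wEdges
  attr(out, "binB") <- rep(ctrB, times = nW)
  attr(out, "binW") <- rep(ctrW, each = nB)
  out
}

#' Match module labels across windows (Hungarian algorithm)
#'
#' Module ids from independent per-window detections are arbitrary. This
#' relabels each window's modules to maximise overlap with the previous
#' (already matched) window, chaining forward through time: the Hungarian
#' algorithm is run on the module-overlap contingency matrix of each
#' consecutive pair. Modules with no overlap to any previous module receive
#' fresh ids. Groupings within each window are unchanged, so per-window Q is
#' preserved exactly.
#'
#' @param parts a [WindowPartitionSet-class] with at least 2 windows.
#' @return the relabeled [WindowPartitionSet-class] (`matched = TRUE`).
#' @export
matchLabels <- function(parts) {
  stopifnot(is(parts, "WindowPartitionSet"))
  A <- parts@assignments
  if (nrow(A) < 2L) stop("need at least 2 windows to match labels")
  out <- A
  nextId <- max(out[1, ]) + 1L
  for (k in 2L:nrow(A)) {
    prev <- out[k - 1L, ]
    cur <- A[k, ]
    pl <- sort(unique(prev)); cl <- sort(unique(cur))
    n <- max(length(pl), length(cl))
    ov <- matrix(0, n, n)  # rows: current modules, cols: previous labels
    for (i in seq_along(cl))
      for (j in seq_along(pl))
        ov[i, j] <- sum(cur == cl[i] & prev == pl[j])
    assign <- hungarianAssignment(max(ov) - ov)
    newLab <- integer(length(cl))
    for (i in seq_along(cl)) {
      j <- assign[i]
      if (j <= length(pl) && ov[i, j] > 0) {
        newLab[i] <- pl[j]
      } else {
        newLab[i] <- nextId
        nextId <- nextId + 1L
      }
    }
    out[k, ] <- newLab[match(cur, cl)]
  }
  new("WindowPartitionSet", assignments = out, Q = parts@Q,
      nModules = parts@nModules, gamma = parts@gamma, matched = TRUE,
      regionLabels = parts@regionLabels)
}

#' Regional flexibility: module-switching rate per region
#'
#' The fraction of window-to-window transitions at which a region's
#' (label-matched) module changes. The `"per_module"` variant additionally
#' divides by the mean per-window module count (a normalisation to the total
#' number of modules); values are clipped at 1. Labels are matched with
#' [matchLabels()] first if they have not been already.
#'
#' @param parts a [WindowPartitionSet-class].
#' @param normalization `"switch_fraction"` (default) or `"per_module"`.
#' @return named numeric vector of per-region flexibility in \[0, 1\], with
#'   attribute `normalization`.
#' @export
regionalFlexibility <- function(parts,
                                normalization = c("switch_fraction",
                                                  "per_module")) {
  normalization <- match.arg(normalization)
  stopifnot(is(parts, "WindowPartitionSet"))
  if (!parts@matched) parts <- matchLabels(parts)
  A <- parts@assignments
  switches <- colSums(A[-1L, , drop = FALSE] != A[-nrow(A), , drop = FALSE])
  flex <- switches / (nrow(A) - 1L)
  if (normalization == "per_module")
    flex <- pmin(flex / mean(parts@nModules), 1)
  names(flex) <- parts@regionLabels
  attr(flex, "normalization") <- normalization
  flex
}
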