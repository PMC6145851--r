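# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with plain loops, never through the package's
# compiled code paths.

# All partitions of n labelled items (restricted-growth strings).
setPartitions <- function(n) {
  parts <- list()
  rec <- function(m, k) {
    if (length(m) == n) {
      parts[[length(parts) + 1L]] <<- m
      return(invisible())
    }
    for (c in seq_len(k + 1L)) rec(c(m, c), max(k, c))
  }
  rec(c(1L), 1L)
  parts
}

# Signed modularity by direct double loop over all ordered pairs.
bruteModularity <- function(W, m, gamma = 1) {
  n <- nrow(W)
  sp <- rowSums(pmax(W, 0)); sn <- rowSums(pmax(-W, 0))
  vp <- sum(sp); vn <- sum(sn)
  Q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (m[i] != m[j]) next
    wp <- max(W[i, j], 0); wn <- max(-W[i, j], 0)
    if (vp > 0) Q <- Q + (wp - gamma * sp[i] * sp[j] / vp) / vp
    if (vn > 0) Q <- Q - (wn - gamma * sn[i] * sn[j] / vn) / (vp + vn)
  }
  Q
}

# Participation coefficient by direct loop (positive weights).
bruteParticipation <- function(W, m) {
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    pos <- pmax(W[i, ], 0); pos[i] <- 0
    ki <- sum(pos)
    if (ki == 0) return(0)
    1 - sum(sapply(unique(m), function(s) (sum(pos[m == s]) / ki)^2))
  })
}

# Module-degree z-score by direct loop (positive weights, population sd).
bruteModuleZ <- function(W, m) {
  n <- nrow(W)
  kap <- sapply(seq_len(n), function(i) {
    pos <- pmax(W[i, ], 0); pos[i] <- 0
    sum(pos[m == m[i]])
  })
  sapply(seq_len(n), function(i) {
    idx <- m == m[i]
    mu <- mean(kap[idx])
    s <- sqrt(mean((kap[idx] - mu)^2))
    if (s > 0) (kap[i] - mu) / s else 0
  })
}

# Minimum-cost assignment by full permutation enumeration.
bruteAssignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  rec <- function(avail, acc) {
    if (!length(avail)) {
      s <- sum(cost[cbind(seq_len(n), acc)])
      if (s < best) best <<- s
      return(invisible())
    }
    for (x in avail) rec(setdiff(avail, x), c(acc, x))
  }
  rec(seq_len(n), integer(0))
  best
}

# BH step-up by scanning every candidate threshold.
bruteBhReject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= q * i / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Random symmetric signed graph with zero diagonal.
randomSignedGraph <- function(n, seed, sd = 0.5) {
  set.seed(seed)
  W <- matrix(rnorm(n * n, sd = sd), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Small strong-modular rest spec used by several suites.
strongSpec <- function(nRegions = 40L, nFrames = 200L, within = 0.9,
                       between = 0.05, seed = 13L, tr = 2.2) {
  sizes <- rep(nRegions %/% 4L, 4L)
  extra <- nRegions - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  syntheticSpec(nRegions = nRegions,
                moduleSizes = sizes,
                tr = tr, nFrames = nFrames, withinCoupling = within,
                betweenCoupling = c(rest = between), seed = seed)
}

# Alternating integration/segregation state sequence (block lengths 15-30).
switchingStates <- function(nFrames, seed) {
  set.seed(seed)
  s <- character(nFrames); cur <- "seg"; i <- 1L
  while (i <= nFrames) {
    len <- sample(15:30, 1)
    s[i:min(nFrames, i + len - 1L)] <- cur
    i <- i + len
    cur <- if (cur == "seg") "int" else "seg"
  }
  s
}

# One synthetic subject for pupil-coupling studies: a switching-state run,
# its windowed bin-occupancy series, and a pupil trace either coupled to the
# latent integration or independent of it.
pupilSubject <- function(seed, independent = FALSE, nBinsB = 5L, nBinsW = 2L) {
  nF <- 216L
  states <- switchingStates(nF, seed)
  spec <- syntheticSpec(nRegions = 20L, moduleSizes = rep(5L, 4L), tr = 2.2,
                        nFrames = nF, withinCoupling = 0.6,
                        betweenCoupling = c(seg = 0.05, int = 0.45),
                        stateSequence = states, seed = seed)
  out <- generateModularBold(spec)
  lat <- if (independent) {
    set.seed(seed + 5000L)
    cumsum(rnorm(nF))
  } else out$groundTruth$latentIntegration
  pup <- generatePupil(lat, tr = 2.2, lag = 2.2, noiseSd = 0.05,
                       seed = seed + 1L)
  tens <- mtdCoupling(out$ts, w = 15)
  parts <- runWindows(tens, gamma = 1.1, nReps = 3, seed = seed)
  topo <- computeTopology(tens, parts)
  bs <- windowOccupancySeries(topo, nB = nBinsB, nW = nBinsW)
  pw <- windowAverage(convolveHrf(pup@samples, 2.2), w = 15, stride = 1,
                      n = nrow(bs))
  list(pw = pw, bs = bs)
}

# A two-session n-back block design (~10 min at TR 2 s) used by task tests.
nbackDesign <- function() {
  data.frame(condition = c("instruction", "0back", "1back", "2back", "3back",
                           "0back", "1back", "2back", "3back"),
             onset = c(0, 20, 60, 100, 140, 180, 220, 260, 300),
             duration = c(10, rep(30, 8)))
}

# Reduced-size crossover cohort analysis used by the power studies: returns
# the per-bin interaction ANOVA of 20 x 20 profile occupancy.
cohortAnova <- function(seed, shift, nSubjects = 20L) {
  spec <- syntheticSpec(nRegions = 20L, moduleSizes = rep(5L, 4L), tr = 2.2,
                        nFrames = 90L, withinCoupling = 0.6,
                        betweenCoupling = c(rest = 0.35), seed = seed)
  coh <- generateCrossoverCohort(nSubjects, spec, drugIntegrationShift = shift,
                                 seed = seed)
  occ <- t(vapply(names(coh$runs), function(id) {
    tens <- mtdCoupling(coh$runs[[id]], w = 15)
    parts <- runWindows(tens, gamma = 1.1, nReps = 3,
                        seed = netdyn:::deriveSeed(seed, id))
    topo <- computeTopology(tens, parts)
    as.numeric(occupancy(cartographicProfile(topo, nB = 20, nW = 20)))
  }, numeric(400)))
  binAnova2x2(occ, coh$meta$subject, coh$meta$session, coh$meta$treatment)
}

# Bin-centre B coordinates for the 20 x 20 profile geometry.
profileBinB <- function(nB = 20L, nW = 20L) {
  e <- seq(0, 1, length.out = nB + 1L)
  rep((e[-1] + e[-(nB + 1L)]) / 2, times = nW)
}
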