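twoCliques <- function() {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  diag(W) <- 0
  W
}

test_that("signed modularity matches exhaustive enumeration on 6 nodes", {
  W <- twoCliques()
  parts <- setPartitions(6L)
  expect_length(parts, 203L)
  qs <- vapply(parts, function(m) bruteModularity(W, m, 1), numeric(1))
  qs2 <- vapply(parts, function(m) signedModularity(W, m, 1), numeric(1))
  expect_lt(max(abs(qs - qs2)), 1e-12)
  planted <- c(1, 1, 1, 2, 2, 2)
  expect_equal(max(qs), signedModularity(W, planted, 1))
  expect_identical(parts[[which.max(qs)]], as.integer(planted))

  # random signed graphs, including gamma != 1
  for (s in 1:6) {
    Wr <- randomSignedGraph(6L, s)
    for (g in c(0.8, 1, 1.4)) {
      qr <- vapply(parts, function(m) signedModularity(Wr, m, g), numeric(1))
      qb <- vapply(parts, function(m) bruteModularity(Wr, m, g), numeric(1))
      expect_lt(max(abs(qr - qb)), 1e-12)
    }
  }
})

test_that("modularity is invariant to label permutation and needs v+ > 0", {
  W <- randomSignedGraph(10L, 7L)
  m <- rep(1:2, 5)
  expect_equal(signedModularity(W, m, 1.1),
               signedModularity(W, 3 - m, 1.1))
  allNeg <- -abs(randomSignedGraph(4L, 8L))
  expect_error(signedModularity(allNeg, rep(1, 4), 1), "positive weight")
  expect_error(louvainOnce(allNeg, 1, 1), "positive weight")
})

test_that("Louvain recovers planted cliques for any seed, deterministically", {
  W <- twoCliques()
  for (s in c(1, 7, 42, 999)) {
    p <- louvainOnce(W, 1, seed = s)
    expect_equal(nmi(p, c(1, 1, 1, 2, 2, 2)), 1)
  }
  Wr <- randomSignedGraph(15L, 9L)
  expect_identical(louvainOnce(Wr, 1, seed = 5L), louvainOnce(Wr, 1, seed = 5L))
})

test_that("Louvain never falls below the all-singletons partition", {
  for (s in 1:20) {
    W <- randomSignedGraph(12L, 100 + s)
    p <- louvainOnce(W, 1, seed = s)
    expect_gte(signedModularity(W, p, 1),
               signedModularity(W, seq_len(12), 1) - 1e-12)
  }
})

test_that("consensus agrees with unambiguous structure and single runs", {
  W <- twoCliques()
  cons <- consensusPartition(W, 1, nReps = 30, seed = 2L)
  expect_equal(nmi(cons$membership, c(1, 1, 1, 2, 2, 2)), 1)
  expect_equal(cons$Q, signedModularity(W, cons$membership, 1))

  Wr <- randomSignedGraph(12L, 11L)
  one <- consensusPartition(Wr, 1, nReps = 1, seed = 6L)
  single <- louvainOnce(Wr, 1, seed = 6L)
  expect_equal(nmi(one$membership, single), 1)
})

test_that("consensus Q is representative of the run ensemble", {
  # On structured and structureless graphs alike, the fine-tuned consensus
  # should rarely fall below the median individual-run Q; structureless
  # graphs occasionally admit ties between basins, so a small failure count
  # is tolerated and the ensemble mean must not degrade.
  diffs <- vapply(1:20, function(g) {
    W <- randomSignedGraph(20L, 200 + g, sd = 0.3)
    qind <- vapply(1:20, function(s)
      signedModularity(W, louvainOnce(W, 1, s), 1), numeric(1))
    cons <- consensusPartition(W, 1, nReps = 20, seed = 99L)
    cons$Q - median(qind)
  }, numeric(1))
  expect_gte(sum(diffs >= -1e-12), 17)
  expect_gte(mean(diffs), 0)
})

test_that("gamma sweep finds a stable plateau on planted structure", {
  W <- netdyn:::blockCovariance(rep(10L, 4L), 0.8, 0.1)
  diag(W) <- 0
  gs <- gammaSweep(W, nIter = 20L, seed = 1L)
  expect_true(all(gs$table$stability > 0.99))
  expect_equal(gs$gamma, 0.5)  # ties resolve to the smallest gamma
  expect_equal(nrow(gs$table), 21L)

  # a structureless graph is less stable at every gamma and clearly so at
  # low resolution (high gamma fragments noise into consistently many
  # singleton-like modules, inflating pairwise NMI)
  Wn <- randomSignedGraph(40L, 2L, sd = 0.3)
  gn <- gammaSweep(Wn, nIter = 15L, seed = 1L)
  expect_true(all(gn$table$stability < gs$table$stability))
  expect_lt(gn$table$stability[1], 0.5)

  # degenerate single-point sweep
  g1 <- gammaSweep(W, lo = 1.0, hi = 1.05, step = 0.5, nIter = 5L, seed = 1L)
  expect_equal(g1$gamma, 1.0)
  expect_equal(nrow(g1$table), 1L)
})

test_that("per-window detection recovers planted modules when windows are informative", {
  spec <- strongSpec(nRegions = 40L, nFrames = 200L, within = 0.9,
                     between = 0.05, seed = 13L)
  out <- generateModularBold(spec)
  tens <- mtdCoupling(out$ts, w = 40)
  parts <- runWindows(tens, gamma = 1.1, nReps = 20, seed = 2L)
  nm <- apply(assignments(parts), 1, function(a)
    nmi(a, out$groundTruth$plantedPartition))
  expect_gte(min(nm), 0.95)
  expect_true(all(moduleCounts(parts) == 4L))
  expect_true(all(is.finite(modularity(parts))))

  # ids are contiguous 1..k within every window
  for (k in seq_len(nWindows(parts)))
    expect_setequal(unique(assignments(parts)[k, ]),
                    seq_len(moduleCounts(parts)[k]))
})

test_that("windowed module counts track merge/split state switching", {
  Btwo <- matrix(0.05, 4, 4)
  Btwo[1, 2] <- Btwo[2, 1] <- Btwo[3, 4] <- Btwo[4, 3] <- 0.85
  states <- rep(rep(c("four", "two"), each = 50), 2)[1:200]
  spec <- syntheticSpec(nRegions = 40L, moduleSizes = rep(10L, 4L), tr = 2.2,
                        nFrames = 200L, withinCoupling = 0.9,
                        betweenCoupling = c(four = 0.05, two = 0.05),
                        stateSequence = states, seed = 14L,
                        betweenMatrices = list(two = Btwo))
  out <- generateModularBold(spec)
  tens <- mtdCoupling(out$ts, w = 40)
  parts <- runWindows(tens, gamma = 1.1, nReps = 10, seed = 3L)
  pure <- vapply(seq_len(nWindows(parts)), function(k) {
    st <- states[pmin(k:(k + 40), 200L)]
    if (all(st == "four")) "four" else if (all(st == "two")) "two" else NA_character_
  }, character(1))
  expect_equal(mean(moduleCounts(parts)[which(pure == "four")]), 4,
               tolerance = 0.15)
  expect_equal(mean(moduleCounts(parts)[which(pure == "two")]), 2,
               tolerance = 0.15)
})

test_that("a one-window tensor yields a partition set of size one", {
  ts <- ParcellatedTimeSeries(matrix(rnorm(6 * 12), 12, 6), tr = 2)
  tens <- mtdCoupling(ts, w = 8, stride = 4L)
  expect_equal(nWindows(tens), 1L)
  parts <- runWindows(tens, nReps = 5, seed = 1L)
  expect_equal(nrow(assignments(parts)), 1L)
})
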