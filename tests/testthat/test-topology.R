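test_that("cartography matches brute-force loop evaluation on random graphs", {
  worstB <- 0; worstW <- 0
  for (s in 1:100) {
    W <- randomSignedGraph(12L, 300 + s)
    m <- sample(rep(1:3, each = 4))
    worstB <- max(worstB, max(abs(participationCoef(W, m) -
                                    bruteParticipation(W, m))))
    worstW <- max(worstW, max(abs(moduleDegreeZscore(W, m) -
                                    bruteModuleZ(W, m))))
  }
  expect_lt(worstB, 1e-12)
  expect_lt(worstW, 1e-12)
})

test_that("participation is 0 for within-module nodes and 1 - 1/n for uniform", {
  W <- matrix(0, 8, 8)
  m <- rep(1:2, each = 4)
  W[1, 2:4] <- W[2:4, 1] <- c(0.5, 1, 2)   # node 1: all links inside module 1
  W[5, 6] <- W[6, 5] <- 1
  expect_equal(participationCoef(W, m)[1], 0)

  # equal positive strength to each of 4 modules
  W4 <- matrix(0, 9, 9)
  m4 <- c(1, 1, 2, 2, 3, 3, 4, 4, 1)
  W4[9, c(1, 3, 5, 7)] <- W4[c(1, 3, 5, 7), 9] <- 2
  expect_equal(participationCoef(W4, m4)[9], 1 - 4 * (1 / 4)^2)

  # isolated node scores 0
  expect_equal(participationCoef(W4, m4)[2], 0)
})

test_that("module-degree z-scores are centred per module", {
  W <- abs(randomSignedGraph(12L, 5L))
  m <- rep(1:3, each = 4)
  z <- moduleDegreeZscore(W, m)
  for (s in 1:3) expect_lt(abs(mean(z[m == s])), 1e-9)

  # a node at its module's mean strength scores 0
  Weq <- matrix(0, 6, 6)
  Weq[1:3, 1:3] <- 1; Weq[4:6, 4:6] <- 1; diag(Weq) <- 0
  expect_equal(moduleDegreeZscore(Weq, rep(1:2, each = 3)), rep(0, 6))
})

test_that("participation grows when strength moves to a new module", {
  W <- matrix(0, 9, 9)
  m <- rep(1:3, each = 3)
  W[1, 2] <- W[2, 1] <- 3
  prev <- participationCoef(W, m)[1]
  for (shift in c(0.5, 1, 1.5)) {
    W2 <- W
    W2[1, 2] <- W2[2, 1] <- 3 - shift
    W2[1, 4] <- W2[4, 1] <- shift
    cur <- participationCoef(W2, m)[1]
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("cartographic profiles are normalised, clipped and localised", {
  B <- matrix(0.5, 4, 3); Wz <- matrix(0, 4, 3)
  topo <- new("TopologySeries", B = B, W = Wz, meanB = rowMeans(B),
              regionLabels = paste0("R", 1:3))
  prof <- cartographicProfile(topo, nB = 10, nW = 10)
  expect_equal(sum(occupancy(prof)), 1)
  expect_equal(max(occupancy(prof)), 1)   # all mass in a single bin
  expect_equal(prof@nClipped, 0L)

  Wz2 <- Wz; Wz2[1, 1] <- 99              # clips into the edge bin
  topo2 <- new("TopologySeries", B = B, W = Wz2, meanB = rowMeans(B),
               regionLabels = paste0("R", 1:3))
  prof2 <- cartographicProfile(topo2, nB = 10, nW = 10)
  expect_equal(prof2@nClipped, 1L)
  expect_equal(sum(occupancy(prof2)), 1)

  empty <- new("TopologySeries", B = matrix(0, 0, 0), W = matrix(0, 0, 0),
               meanB = numeric(0), regionLabels = character(0))
  expect_error(cartographicProfile(empty), "empty")
})

test_that("integrated runs shift profile mass toward higher B", {
  mk <- function(between, seed) {
    spec <- syntheticSpec(nRegions = 20L, moduleSizes = rep(5L, 4L), tr = 2.2,
                          nFrames = 120L, withinCoupling = 0.6,
                          betweenCoupling = c(rest = between), seed = seed)
    ts <- generateModularBold(spec)$ts
    tens <- mtdCoupling(ts, w = 15)
    parts <- runWindows(tens, gamma = 1.1, nReps = 5, seed = seed)
    topo <- computeTopology(tens, parts)
    prof <- cartographicProfile(topo, nB = 20, nW = 20)
    ctr <- profileBinB()
    sum(rowSums(occupancy(prof)) * unique(ctr))
  }
  integrated <- vapply(1:5, function(s) mk(0.45, s), numeric(1))
  segregated <- vapply(1:5, function(s) mk(0.05, 100 + s), numeric(1))
  expect_true(all(integrated > segregated))
})

test_that("per-window occupancy rows are proper distributions", {
  spec <- strongSpec(nRegions = 16L, nFrames = 60L)
  ts <- generateModularBold(spec)$ts
  tens <- mtdCoupling(ts, w = 15)
  parts <- runWindows(tens, nReps = 3, seed = 1L)
  topo <- computeTopology(tens, parts)
  bs <- windowOccupancySeries(topo, nB = 5, nW = 4)
  expect_equal(rowSums(bs), rep(1, nrow(bs)))
  expect_length(attr(bs, "binB"), 20L)
})

test_that("label matching aligns permuted labels and preserves Q", {
  A <- rbind(c(1, 1, 2, 2, 3, 3),
             c(2, 2, 3, 3, 1, 1),
             c(3, 3, 1, 1, 2, 2))
  ps <- new("WindowPartitionSet", assignments = A, Q = c(0.3, 0.31, 0.29),
            nModules = rep(3L, 3), gamma = 1.1, matched = FALSE,
            regionLabels = paste0("R", 1:6))
  m <- matchLabels(ps)
  expect_true(m@matched)
  expect_equal(assignments(m)[2, ], assignments(m)[1, ])
  expect_equal(assignments(m)[3, ], assignments(m)[1, ])
  expect_identical(modularity(m), modularity(ps))
  expect_error(matchLabels(new("WindowPartitionSet",
                               assignments = A[1, , drop = FALSE], Q = 0.3,
                               nModules = 3L, gamma = 1, matched = FALSE,
                               regionLabels = paste0("R", 1:6))),
               "2 windows")
})

test_that("a single migrating region changes only its own matched label", {
  base <- rep(c(1L, 2L), each = 3)
  A <- rbind(base, base, base)
  # window 2: region 1 joins the second group AND ids are globally permuted
  A[2, ] <- c(1L, 2L, 2L, 1L, 1L, 1L)
  ps <- new("WindowPartitionSet", assignments = A, Q = rep(0, 3),
            nModules = rep(2L, 3), gamma = 1, matched = FALSE,
            regionLabels = paste0("R", 1:6))
  m <- assignments(matchLabels(ps))
  expect_equal(m[2, 2:6], m[1, 2:6])
  expect_false(m[2, 1] == m[1, 1])
})

test_that("flexibility counts matched module switches", {
  base <- rep(c(1L, 2L), each = 3)
  A <- matrix(rep(base, 10), nrow = 10, byrow = TRUE)
  ps0 <- new("WindowPartitionSet", assignments = A, Q = rep(0, 10),
             nModules = rep(2L, 10), gamma = 1, matched = FALSE,
             regionLabels = paste0("R", 1:6))
  expect_equal(as.numeric(regionalFlexibility(ps0)), rep(0, 6))

  # constant grouping under per-window label permutations is still 0
  Aperm <- A
  Aperm[c(2, 5, 7), ] <- 3L - Aperm[c(2, 5, 7), ]
  psP <- new("WindowPartitionSet", assignments = Aperm, Q = rep(0, 10),
             nModules = rep(2L, 10), gamma = 1, matched = FALSE,
             regionLabels = paste0("R", 1:6))
  expect_equal(as.numeric(regionalFlexibility(psP)), rep(0, 6))

  # region 1 changes matched module at exactly 4 of the 9 transitions
  # (out at t1, back at t2, out at t3, back at t4, then settled)
  A49 <- A
  A49[c(2, 4), 1] <- 2L
  ps49 <- new("WindowPartitionSet", assignments = A49, Q = rep(0, 10),
              nModules = rep(2L, 10), gamma = 1, matched = FALSE,
              regionLabels = paste0("R", 1:6))
  f <- regionalFlexibility(ps49)
  expect_equal(as.numeric(f[1]), 4 / 9)
  expect_equal(as.numeric(f[2]), 0)

  pm <- regionalFlexibility(ps49, normalization = "per_module")
  expect_equal(attr(pm, "normalization"), "per_module")
  expect_equal(as.numeric(pm[1]), (4 / 9) / 2)
})
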