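test_that("long simulations reproduce the target block covariance", {
  spec <- syntheticSpec(nRegions = 40L, moduleSizes = rep(10L, 4L), tr = 2.2,
                        nFrames = 2000L, withinCoupling = 0.8,
                        betweenCoupling = c(rest = 0.1), seed = 11L)
  out <- generateModularBold(spec)
  C <- cor(tsData(out$ts))
  m <- out$groundTruth$plantedPartition
  same <- outer(m, m, "==") & row(C) != col(C)
  expect_lt(abs(mean(C[same]) - 0.8), 0.05)
  expect_lt(abs(mean(C[!same & row(C) != col(C)]) - 0.1), 0.05)
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- strongSpec(nRegions = 20L, nFrames = 60L, seed = 5L)
  a <- generateModularBold(spec)
  b <- generateModularBold(spec)
  expect_identical(tsData(a$ts), tsData(b$ts))
  spec2 <- strongSpec(nRegions = 20L, nFrames = 60L, seed = 6L)
  expect_false(identical(tsData(a$ts), tsData(generateModularBold(spec2)$ts)))
})

test_that("between == within removes community structure", {
  spec <- syntheticSpec(nRegions = 40L, moduleSizes = rep(10L, 4L), tr = 2.2,
                        nFrames = 400L, withinCoupling = 0.4,
                        betweenCoupling = c(rest = 0.4), seed = 3L)
  out <- generateModularBold(spec)
  W <- meanCouplingGraph(out$ts, w = 15)
  cons <- consensusPartition(W, gamma = 1.1, nReps = 20, seed = 1L)
  planted <- out$groundTruth$plantedPartition
  obs <- nmi(cons$membership, planted)
  # chance level for finite partitions is not zero: compare against the
  # permutation null of the planted labels
  set.seed(2)
  nullNmi <- replicate(200, nmi(cons$membership, sample(planted)))
  expect_lte(obs, quantile(nullNmi, 0.95) + 1e-12)
  expect_lt(obs, 0.5)
})

test_that("non-PSD target covariance fails naming the offending state", {
  expect_error(
    syntheticSpec(nRegions = 20L, moduleSizes = rep(5L, 4L),
                  withinCoupling = 0.1, betweenCoupling = c(wild = 0.9),
                  nFrames = 10L),
    "wild")
})

test_that("planted partition covers all regions exactly once", {
  spec <- strongSpec(nRegions = 24L, nFrames = 50L)
  gt <- generateModularBold(spec)$groundTruth
  expect_length(gt$plantedPartition, 24L)
  expect_setequal(unique(gt$plantedPartition), 1:4)
  expect_length(gt$latentIntegration, 50L)
})

test_that("noiseless pupil is a perfect lagged monotone copy of the latent", {
  lat <- sin(seq(0, 6 * pi, length.out = 300)) + 0.2
  pup <- generatePupil(lat, tr = 2.2, lag = 4.4, noiseSd = 0, seed = 1L)
  k <- round(4.4 / 2.2)
  rho <- cor(pup@samples[(k + 1):300], lat[1:(300 - k)], method = "spearman")
  expect_equal(rho, 1)
  expect_true(pup@zScored)
  expect_equal(mean(pup@samples), 0, tolerance = 1e-9)
})

test_that("dominant pupil noise destroys the latent correlation", {
  lat <- sin(seq(0, 6 * pi, length.out = 2000))
  rhos <- vapply(1:40, function(s) {
    pup <- generatePupil(lat, tr = 2.2, lag = 0, noiseSd = 10 * sd(lat),
                         seed = s)
    cor(pup@samples, lat, method = "spearman")
  }, numeric(1))
  expect_lt(max(abs(rhos)), 0.2)
  expect_identical(generatePupil(lat, 2.2, 0, 1, seed = 9L)@samples,
                   generatePupil(lat, 2.2, 0, 1, seed = 9L)@samples)
})

test_that("task runs follow the load-integration profile", {
  spec <- strongSpec(nRegions = 20L, nFrames = 150L, within = 0.6,
                     between = 0.1, tr = 2.0, seed = 8L)
  prof <- c(`0back` = 0.1, `1back` = 0.3, `2back` = 0.5, `3back` = 0.3)
  design <- data.frame(condition = c("0back", "2back"),
                       onset = c(20, 150), duration = c(60, 60))
  out <- generateTaskRun(spec, design, prof)
  lat <- out$groundTruth$latentIntegration
  centers <- (seq_len(150) - 0.5) * 2.0
  in2back <- centers >= 150 & centers < 210
  expect_true(all(lat[in2back] == 0.5))
  expect_true(all(lat[centers < 20] == 0.1))

  # empty design is a pure baseline run, identical to the rest generator
  base <- generateTaskRun(spec, design[0, ], prof)
  expect_identical(tsData(base$ts), tsData(generateModularBold(spec)$ts))

  # overlapping or out-of-run blocks fail
  expect_error(generateTaskRun(spec, data.frame(
    condition = c("0back", "1back"), onset = c(10, 30), duration = c(40, 30)),
    prof), "overlap")
  expect_error(generateTaskRun(spec, data.frame(
    condition = "3back", onset = 290, duration = 60), prof), "beyond")
})

test_that("crossover cohorts are complete, shifted and reproducible", {
  spec <- strongSpec(nRegions = 12L, nFrames = 40L, within = 0.6,
                     between = 0.35)
  coh <- generateCrossoverCohort(3L, spec, drugIntegrationShift = -0.3,
                                 seed = 17L, subjectSd = 0.02)
  expect_equal(nrow(coh$meta), 12L)
  expect_true(all(table(coh$meta$subject, coh$meta$session,
                        coh$meta$treatment) == 1))
  m <- coh$meta
  postDrug <- m$betweenCoupling[m$session == "post" & m$treatment == "drug"]
  preDrug <- m$betweenCoupling[m$session == "pre" & m$treatment == "drug"]
  expect_equal(postDrug - preDrug, rep(-0.3, 3L))
  coh2 <- generateCrossoverCohort(3L, spec, drugIntegrationShift = -0.3,
                                  seed = 17L, subjectSd = 0.02)
  expect_identical(lapply(coh$runs, tsData), lapply(coh2$runs, tsData))
})

test_that("per-pair coupling matrices let module pairs merge", {
  Btwo <- matrix(0.05, 4, 4)
  Btwo[1, 2] <- Btwo[2, 1] <- Btwo[3, 4] <- Btwo[4, 3] <- 0.85
  spec <- syntheticSpec(nRegions = 20L, moduleSizes = rep(5L, 4L), tr = 2.2,
                        nFrames = 600L, withinCoupling = 0.9,
                        betweenCoupling = c(two = 0.05), seed = 21L,
                        betweenMatrices = list(two = Btwo))
  out <- generateModularBold(spec)
  C <- cor(tsData(out$ts))
  expect_gt(mean(C[1:5, 6:10]), 0.7)   # merged pair
  expect_lt(mean(C[1:5, 11:15]), 0.2)  # unmerged pair
})
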