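test_that("BH step-up matches direct evaluation and a brute-force scan", {
  r <- fdrBh(c(0.001, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(sum(r$reject), 3L)
  expect_equal(r$threshold, 0.03)
  expect_false(any(fdrBh(rep(1, 10), 0.05)$reject))
  expect_length(fdrBh(numeric(0))$reject, 0L)
  expect_error(fdrBh(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(30)
  for (i in 1:300) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    r <- fdrBh(p, q = 0.05)
    expect_identical(r$reject, bruteBhReject(p, 0.05))
    # order invariance
    o <- sample(length(p))
    expect_identical(fdrBh(p[o], 0.05)$reject, r$reject[o])
  }
})

test_that("crossover interaction F equals the squared paired contrast t", {
  set.seed(31)
  n <- 14L
  occ <- matrix(rnorm(n * 4 * 30), n * 4, 30)
  subject <- rep(seq_len(n), each = 4)
  session <- rep(c("pre", "post"), 2 * n)
  treatment <- rep(rep(c("drug", "placebo"), each = 2), n)
  an <- binAnova2x2(occ, subject, session, treatment)
  key <- paste(session, treatment)
  for (b in seq_len(30)) {
    y <- occ[, b]
    d <- (y[key == "post drug"] - y[key == "pre drug"]) -
      (y[key == "post placebo"] - y[key == "pre placebo"])
    tstat <- mean(d) / (sd(d) / sqrt(n))
    expect_lt(abs(an$F[b] - tstat^2), 1e-9)
  }
  expect_equal(an$delta, colMeans(
    occ[key == "post drug", ] - occ[key == "pre drug", ] -
      occ[key == "post placebo", ] + occ[key == "pre placebo", ]))
})

test_that("degenerate and incomplete crossover inputs are handled", {
  n <- 6L
  base <- matrix(rep(rnorm(n), each = 4), n * 4, 5)  # identical cells
  subject <- rep(seq_len(n), each = 4)
  session <- rep(c("pre", "post"), 2 * n)
  treatment <- rep(rep(c("drug", "placebo"), each = 2), n)
  an <- binAnova2x2(base, subject, session, treatment)
  expect_true(all(an$F == 0))
  expect_false(any(an$reject))

  expect_error(binAnova2x2(base[-1, ], subject[-1], session[-1],
                           treatment[-1]), "sub.*1|1")
})

test_that("pupil-coupled cohorts show positive high-B correlations", {
  hits <- vapply(1:12, function(sd0) {
    subs <- lapply(1:8, function(s)
      pupilSubject(netdyn:::deriveSeed(sd0, paste0("s", s))))
    res <- pupilTopologyCorrelation(lapply(subs, `[[`, "pw"),
                                    lapply(subs, `[[`, "bs"))
    binB <- attr(subs[[1]]$bs, "binB")
    any(res$perBin$reject & res$perBin$estimate > 0 & binB > 0.6,
        na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("independent pupil traces stay at the FDR floor", {
  fracs <- vapply(1:40, function(sd0) {
    subs <- lapply(1:8, function(s)
      pupilSubject(netdyn:::deriveSeed(sd0, paste0("n", s)),
                   independent = TRUE))
    res <- pupilTopologyCorrelation(lapply(subs, `[[`, "pw"),
                                    lapply(subs, `[[`, "bs"))
    mean(res$perBin$reject, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(fracs), 0.07)
})

test_that("a pupil identical to a bin series correlates perfectly", {
  set.seed(33)
  bs <- matrix(runif(50 * 4), 50, 4)
  pw <- bs[, 2]
  res <- pupilTopologyCorrelation(list(pw, bs[, 2] + 0.01), list(bs, bs))
  expect_equal(res$rho[1, 2], 1)
})

test_that("task GLM recovers noise-free regressors and matches the RSS oracle", {
  design <- nbackDesign()
  tr <- 2.0; nF <- 180L; w <- 15L
  nWin <- (nF - 1) - w + 1
  Xd <- netdyn:::taskDesignMatrix(design, tr, nF, w, nWin)
  set.seed(34)
  Y <- cbind(Xd[, "1back"], rnorm(nWin))
  glm <- taskGlm(Y, design, tr = tr, nFrames = nF, w = w)
  expect_equal(unname(glm$betas["1back", 1]), 1, tolerance = 1e-9)
  others <- setdiff(rownames(glm$betas), c("1back", "(Intercept)"))
  expect_lt(max(abs(glm$betas[others, 1])), 1e-9)

  # F via coefficient covariance equals a full-vs-reduced RSS comparison,
  # where the reduced model constrains the contrast to zero by regressing
  # on a null-space basis of the contrast row
  X <- cbind(1, Xd)
  cvec <- rep(0, ncol(X))
  names(cvec) <- colnames(X)
  cvec[c("0back", "1back", "2back", "3back")] <- c(-1, 1 / 3, 1 / 3, 1 / 3)
  Nbasis <- svd(rbind(cvec), nv = ncol(X))$v[, -1, drop = FALSE]
  # unit 1 is noise-free (its RSS is ~0, so F is numerically unbounded);
  # the RSS comparison is meaningful on the noisy unit
  for (u in 2L) {
    y <- Y[, u]
    rssFull <- sum(lm.fit(X, y)$residuals^2)
    rssRed <- sum(lm.fit(X %*% Nbasis, y)$residuals^2)
    Foracle <- (rssRed - rssFull) / (rssFull / (nWin - ncol(X)))
    expect_equal(glm$main$F[u], Foracle, tolerance = 1e-6)
  }

  # rank deficiency is named
  expect_error(taskGlm(Y, design, tr = tr, nFrames = nF, w = w,
                       nuisance = cbind(dup = Xd[, "2back"])), "dup")
  expect_error(taskGlm(Y, design[design$condition == "instruction", ],
                       tr = tr, nFrames = nF, w = w), "n-back")
})

test_that("inverted-U load profiles load on the main, not the linear, contrast", {
  design <- nbackDesign()
  runGlm <- function(seed, prof) {
    spec <- syntheticSpec(nRegions = 20L, moduleSizes = rep(5L, 4L), tr = 2.0,
                          nFrames = 180L, withinCoupling = 0.6,
                          betweenCoupling = c(rest = 0.05), seed = seed)
    out <- generateTaskRun(spec, design, prof)
    tens <- mtdCoupling(out$ts, w = 15)
    parts <- runWindows(tens, gamma = 1.1, nReps = 3, seed = seed)
    topo <- computeTopology(tens, parts)
    taskGlm(matrix(meanParticipation(topo)), design, tr = 2.0,
            nFrames = 180L, w = 15L)
  }
  uProf <- c(`0back` = 0.05, `1back` = 0.35, `2back` = 0.55, `3back` = 0.35)
  linProf <- c(`0back` = 0.05, `1back` = 0.2, `2back` = 0.4, `3back` = 0.6)
  uRes <- vapply(1:25, function(s) {
    g <- runGlm(s, uProf)
    c(main = g$main$F[1], load = g$load$F[1])
  }, numeric(2))
  linRes <- vapply(1:25, function(s) {
    g <- runGlm(100 + s, linProf)
    c(main = g$main$F[1], load = g$load$F[1])
  }, numeric(2))
  expect_gt(mean(uRes["main", ] > uRes["load", ]), 0.5)
  expect_gt(mean(linRes["load", ] > linRes["main", ]), 0.5)
  expect_gt(median(uRes["main", ]), 10)   # the effect itself is strong
})

test_that("permutation correlation test is exact for self-correlation", {
  set.seed(35)
  x <- rnorm(20)
  res <- permutationCorrTest(x, x, nPerm = 500L, seed = 1L)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 501)
  y2 <- rnorm(20)
  expect_identical(permutationCorrTest(x, y2, 200L, seed = 7L)$p,
                   permutationCorrTest(x, y2, 200L, seed = 7L)$p)
  expect_error(permutationCorrTest(rep(1, 10), rnorm(10)), "constant")
})

test_that("bootstrap CI is degenerate for perfect correlation and seeded", {
  set.seed(36)
  x <- rnorm(30)
  res <- bootstrapCorrCi(x, x, nBoot = 200L, seed = 2L)
  expect_equal(res$ci, c(1, 1))
  y <- 0.5 * x + rnorm(30)
  expect_identical(bootstrapCorrCi(x, y, 300L, seed = 3L)$ci,
                   bootstrapCorrCi(x, y, 300L, seed = 3L)$ci)
})

test_that("Dunn and Clark z is null at equality and matches a permutation reference", {
  expect_equal(dunnClarkZ(0.4, 0.4, 100, 100)$z, 0)
  expect_equal(dunnClarkZ(0.4, 0.4, 100, 100)$p, 1)
  expect_error(dunnClarkZ(1, 0.5, 50, 50), "degenerate")
  expect_error(dunnClarkZ(0.5, 0.2, 50, 60, rCross = 0.3), "equal sample")

  set.seed(37)
  n <- 40L
  x1 <- rnorm(n); y1 <- 0.6 * x1 + rnorm(n, sd = 0.8)
  x2 <- rnorm(n); y2 <- 0.1 * x2 + rnorm(n)
  r1 <- cor(x1, y1); r2 <- cor(x2, y2)
  dc <- dunnClarkZ(r1, r2, n, n)
  pool <- rbind(cbind(x1, y1), cbind(x2, y2))
  obs <- abs(atanh(r1) - atanh(r2))
  permp <- mean(replicate(3000, {
    idx <- sample(2 * n)
    a <- pool[idx[1:n], ]; b <- pool[idx[(n + 1):(2 * n)], ]
    abs(atanh(cor(a[, 1], a[, 2])) - atanh(cor(b[, 1], b[, 2]))) >= obs
  }))
  expect_lt(abs(dc$p - permp), 0.02)
})
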