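#' Build and validate a run configuration
#'
#' A single config drives an end-to-end run: the synthetic cohort recipe (or
#' input paths), MTD window, resolution, consensus repetitions, histogram
#' geometry, null-model settings, statistics settings, and the master seed
#' from which every stage seed is derived. The config round-trips losslessly
#' through JSON via [writeRunConfig()]/[readRunConfig()].
#'
#' @param synthetic list(nSubjects, nRegions, moduleSizes, tr, nFrames,
#'   withinCoupling, betweenCoupling, noiseSd, drugShift, subjectSd) for a
#'   crossover cohort; task pipelines add `design` (data.frame) and
#'   `loadProfile` (named numeric).
#' @param w MTD window length (default 15).
#' @param gamma resolution (default 1.1).
#' @param nReps consensus repetitions per window (default 500).
#' @param bins list(nB, nW, bRange, wRange) histogram geometry.
#' @param filter c(low, high) band edges in Hz, or NULL to skip filtering.
#' @param nulls list(enabled, order, nSurrogates, variant).
#' @param q FDR level.
#' @param seed master seed.
#' @return validated config (class `netdynConfig`).
#' @export
runConfig <- function(synthetic, w = 15L, gamma = 1.1, nReps = 500L,
                      bins = list(nB = 20L, nW = 20L, bRange = c(0, 1),
                                  wRange = c(-5, 5)),
                      filter = NULL,
                      nulls = list(enabled = FALSE, order = 6L,
                                   nSurrogates = 2500L, variant = "diff"),
                      q = 0.05, seed = 1L) {
  cfg <- list(synthetic = synthetic, w = as.integer(w), gamma = gamma,
              nReps = as.integer(nReps), bins = bins, filter = filter,
              nulls = nulls, q = q, seed = as.integer(seed))
  validateConfig(cfg)
  class(cfg) <- "netdynConfig"
  cfg
}

validateConfig <- function(cfg) {
  syn <- cfg$synthetic
  if (is.null(syn)) stop("config validation: `synthetic` block is required")
  for (f in c("nSubjects", "tr", "nFrames", "nRegions"))
    if (is.null(syn[[f]]))
      stop("config validation: synthetic$", f, " is missing")
  if (!is.numeric(syn$tr) || syn$tr <= 0)
    stop("config validation: synthetic$tr must be a positive number of seconds")
  if (is.null(cfg$seed)) stop("config validation: `seed` is required")
  invisible(TRUE)
}

#' @rdname runConfig
#' @param cfg a config; `path` a JSON file path.
#' @param path file path.
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$synthetic$design))
    cfg$synthetic$design <- as.data.frame(cfg$synthetic$design)
  validateConfig(cfg)
  class(cfg) <- "netdynConfig"
  cfg
}

cohortSpecOf <- function(syn, seed) {
  syntheticSpec(nRegions = syn$nRegions,
                moduleSizes = if (!is.null(syn$moduleSizes))
                  as.integer(syn$moduleSizes) else NULL,
                tr = syn$tr, nFrames = syn$nFrames,
                withinCoupling = syn$withinCoupling %||% 0.5,
                betweenCoupling = c(rest = syn$betweenCoupling %||% 0.1),
                noiseSd = syn$noiseSd %||% 0,
                seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeTsv <- function(x, path, rowNames = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = rowNames,
              col.names = TRUE)
  invisible(path)
}

# One run through filter -> MTD -> communities -> topology. Returns the
# stage objects; persistence is handled by the pipeline drivers.
analyseRun <- function(ts, cfg, runSeed) {
  if (!is.null(cfg$filter))
    ts <- bandpassFilter(ts, cfg$filter[1], cfg$filter[2])
  tensor <- mtdCoupling(ts, w = cfg$w)
  parts <- runWindows(tensor, gamma = cfg$gamma, nReps = cfg$nReps,
                      seed = runSeed)
  topo <- computeTopology(tensor, parts)
  list(tensor = tensor, parts = parts, topo = topo)
}

persistRun <- function(res, cfg, dir, id) {
  b <- cfg$bins
  prof <- cartographicProfile(res$topo, nB = b$nB, nW = b$nW,
                              bRange = b$bRange, wRange = b$wRange)
  flex <- regionalFlexibility(res$parts)
  writeTsv(data.frame(window = seq_along(res$parts@Q), Q = res$parts@Q,
                      nModules = res$parts@nModules),
           file.path(dir, paste0(id, "_Q.tsv")))
  writeTsv(as.data.frame(res$topo@B), file.path(dir, paste0(id, "_B.tsv")))
  writeTsv(as.data.frame(res$topo@W), file.path(dir, paste0(id, "_W.tsv")))
  writeTsv(data.frame(region = names(flex), flexibility = as.numeric(flex)),
           file.path(dir, paste0(id, "_flexibility.tsv")))
  writeTsv(as.data.frame(occupancy(prof)),
           file.path(dir, paste0(id, "_profile.tsv")))
  prof
}

provenance <- function(cfg, stageSeeds, outDir) {
  rec <- list(configDigest = rlangHash(unclass(cfg)),
              packageVersion = as.character(utils::packageVersion("netdyn")),
              stageSeeds = stageSeeds)
  jsonlite::write_json(rec, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Deterministic config digest without an external hashing dependency:
# serialize deparsed content and fold into hex.
rlangHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 1469598103934665603
  for (b in as.integer(raw[seq(1, length(raw), by = max(1, length(raw) %/% 4096))])) {
    h <- (h * 1099511 + b) %% 2^48
  }
  paste0(format(h %/% 2^24, scientific = FALSE),
         "-", format(h %% 2^24, scientific = FALSE))
}

#' Run the resting-state crossover pipeline end to end
#'
#' Generates (or loads) a crossover cohort, runs every run through
#' filtering, MTD, per-window community detection and cartography, writes
#' per-run topology, flexibility and profile tables, performs the per-bin
#' 2x2 session-by-treatment ANOVA across the cohort and (optionally) the
#' VAR surrogate dynamism test on the first pre-placebo run. All outputs and
#' the provenance record are deterministic functions of the config.
#'
#' @param cfg a config from [runConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the cohort meta table, the ANOVA map and
#'   the null-test result (or NULL).
#' @export
runRestPipeline <- function(cfg, outDir) {
  validateConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  syn <- cfg$synthetic
  spec <- cohortSpecOf(syn, deriveSeed(cfg$seed, "cohort"))
  cohort <- generateCrossoverCohort(syn$nSubjects, spec,
                                    drugIntegrationShift = syn$drugShift %||% 0,
                                    seed = deriveSeed(cfg$seed, "cohort"),
                                    subjectSd = syn$subjectSd %||% 0.02)
  writeTsv(cohort$meta, file.path(outDir, "cohort_meta.tsv"))
  occ <- NULL
  stageSeeds <- list()
  for (id in names(cohort$runs)) {
    runSeed <- deriveSeed(cfg$seed, paste0("analyse-", id))
    stageSeeds[[id]] <- runSeed
    res <- analyseRun(cohort$runs[[id]], cfg, runSeed)
    prof <- persistRun(res, cfg, outDir, id)
    occ <- rbind(occ, as.numeric(occupancy(prof)))
  }
  an <- binAnova2x2(occ, subject = cohort$meta$subject,
                    session = cohort$meta$session,
                    treatment = cohort$meta$treatment, q = cfg$q)
  writeTsv(an, file.path(outDir, "anova_interaction.tsv"))
  nullRes <- NULL
  if (isTRUE(cfg$nulls$enabled)) {
    ref <- cohort$runs[[which(cohort$meta$session == "pre" &
                                cohort$meta$treatment == "placebo")[1]]]
    if (!is.null(cfg$filter))
      ref <- bandpassFilter(ref, cfg$filter[1], cfg$filter[2])
    model <- fitVar(ref, order = cfg$nulls$order %||% 6L,
                    subspaceDim = cfg$nulls$subspaceDim %||% 50L)
    cons <- consensusPartition(meanCouplingGraph(ref, cfg$w),
                               gamma = cfg$gamma, nReps = cfg$nReps,
                               seed = deriveSeed(cfg$seed, "null-partition"))
    surr <- simulateVar(model, nFrames = nFrames(ref),
                        nSurrogates = cfg$nulls$nSurrogates %||% 2500L,
                        seed = deriveSeed(cfg$seed, "null-surrogates"),
                        bandpass = cfg$filter)
    obsB <- meanParticipationSeries(ref, cons$membership, w = cfg$w)
    surrB <- vapply(seq_len(dim(surr)[3]), function(s)
      meanParticipationSeries(surr[, , s], cons$membership, w = cfg$w),
      numeric(length(obsB)))
    nullRes <- kurtosisTest(obsB, surrB,
                            variant = cfg$nulls$variant %||% "diff")
    jsonlite::write_json(
      list(statistic = nullRes$statistic, threshold = nullRes$threshold,
           significant = nullRes$significant, variant = nullRes$variant,
           percentile = nullRes$percentile),
      file.path(outDir, "null_test.json"), auto_unbox = TRUE, digits = NA)
  }
  provenance(cfg, stageSeeds, outDir)
  invisible(list(meta = cohort$meta, anova = an, nullTest = nullRes))
}

#' Time-averaged coupling graph of a run
#'
#' The mean MTD coupling matrix over all windows: the time-averaged signed
#' graph used for gamma calibration and for fixing a reference partition.
#'
#' @param ts a [ParcellatedTimeSeries-class].
#' @param w MTD window length.
#' @return symmetric signed matrix with zero diagonal.
#' @export
meanCouplingGraph <- function(ts, w = 15L) {
  tensor <- mtdCoupling(ts, w = w)
  W <- apply(tensor@coupling, c(1, 2), mean)
  diag(W) <- 0
  W
}

#' Run the task-based pipeline end to end
#'
#' Generates a two-session (drug/placebo) task cohort whose between-module
#' coupling follows each block's load, runs the network pipeline on each
#' run, fits the windowed task GLM on regional participation, and writes
#' per-run main- and load-effect maps plus per-subject block-wise mean
#' participation.
#'
#' @param cfg a config whose `synthetic` block includes `design` and
#'   `loadProfile`.
#' @param outDir output directory.
#' @return invisibly, list with meta, per-run GLM summaries and block means.
#' @export
runTaskPipeline <- function(cfg, outDir) {
  validateConfig(cfg)
  syn <- cfg$synthetic
  if (is.null(syn$design) || nrow(as.data.frame(syn$design)) == 0)
    stop("task pipeline requires a non-empty synthetic$design")
  design <- as.data.frame(syn$design)
  if (!any(as.character(design$condition) %in%
           c("0back", "1back", "2back", "3back")))
    stop("task design contains no n-back blocks")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  loadProfile <- unlist(syn$loadProfile)
  glms <- list(); blockMeans <- NULL
  meta <- NULL
  for (s in seq_len(syn$nSubjects)) {
    for (trt in c("placebo", "drug")) {
      runSeed <- deriveSeed(cfg$seed, sprintf("task-%d-%s", s, trt))
      prof <- loadProfile
      if (trt == "drug") prof <- prof + (syn$drugShift %||% 0)
      prof[prof < 0] <- 0
      spec <- cohortSpecOf(syn, runSeed)
      out <- generateTaskRun(spec, design, prof)
      id <- sprintf("sub%02d_%s", s, trt)
      res <- analyseRun(out$ts, cfg, deriveSeed(cfg$seed, paste0("analyse-", id)))
      glm <- taskGlm(participation(res$topo), design, tr = syn$tr,
                     nFrames = syn$nFrames, w = cfg$w, q = cfg$q)
      writeTsv(glm$main, file.path(outDir, paste0(id, "_main.tsv")))
      writeTsv(glm$load, file.path(outDir, paste0(id, "_load.tsv")))
      glms[[id]] <- glm
      bm <- blockMeanParticipation(res$topo, design, syn$tr, cfg$w)
      blockMeans <- rbind(blockMeans,
                          data.frame(subject = s, treatment = trt,
                                     t(bm), check.names = FALSE))
      meta <- rbind(meta, data.frame(run = id, subject = s, treatment = trt))
    }
  }
  writeTsv(blockMeans, file.path(outDir, "block_meanB.tsv"))
  provenance(cfg, list(), outDir)
  invisible(list(meta = meta, glms = glms, blockMeans = blockMeans))
}

#' Mean participation per task block condition
#'
#' Averages the per-window mean participation coefficient over the windows
#' whose frame span falls mostly inside each condition's blocks.
#'
#' @param topo a [TopologySeries-class].
#' @param design task block design (condition/onset/duration).
#' @param tr repetition time (s).
#' @param w MTD window length used.
#' @return named vector: per-condition mean of mean-B.
#' @export
blockMeanParticipation <- function(topo, design, tr, w = 15L) {
  design <- as.data.frame(design)
  nWin <- nrow(topo@B)
  # window k spans frames k..k+w; use its centre time
  ctr <- (seq_len(nWin) + w / 2) * tr
  conds <- unique(as.character(design$condition))
  out <- vapply(conds, function(cn) {
    sel <- rep(FALSE, nWin)
    for (b in which(design$condition == cn))
      sel <- sel | (ctr >= design$onset[b] &
                      ctr < design$onset[b] + design$duration[b])
    if (!any(sel)) return(NA_real_)
    mean(topo@meanB[sel])
  }, numeric(1))
  names(out) <- conds
  out
}

#' Compare rest and task regional effect maps
#'
#' Pearson correlation between two per-region effect vectors with a seeded
#' permutation p-value and a bootstrap confidence interval - the
#' cross-study comparison of drug effects on topology.
#'
#' @param restEffect,taskEffect per-region effect estimates.
#' @param nPerm,nBoot,seed see [permutationCorrTest()] and
#'   [bootstrapCorrCi()].
#' @return list with `r`, `p`, `ci`.
#' @export
compareRestTask <- function(restEffect, taskEffect, nPerm = 5000L,
                            nBoot = 1000L, seed = 1L) {
  pt <- permutationCorrTest(restEffect, taskEffect, nPerm = nPerm,
                            seed = deriveSeed(seed, "perm"))
  bc <- bootstrapCorrCi(restEffect, taskEffect, nBoot = nBoot,
                        seed = deriveSeed(seed, "boot"))
  list(r = pt$r, p = pt$p, ci = bc$ci)
}
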