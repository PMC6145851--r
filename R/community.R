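# The community-detection surface works on plain symmetric weight matrices
# ("signed graphs"): signed weighted adjacency with zero diagonal. Helpers
# below validate and strip the diagonal.
asSignedGraph <- function(W) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-10) stop("weight matrix must be symmetric")
  diag(W) <- 0
  if (sum(W[W > 0]) <= 0)
    stop("modularity undefined: graph has no positive weight")
  W
}

#' Signed weighted modularity
#'
#' Quality of a partition of a signed graph, with the positive and negative
#' layers treated asymmetrically:
#' `Q = (1/v+) sum_ij (w+_ij - g*e+_ij) d_ij - (1/(v+ + v-)) sum_ij (w-_ij - g*e-_ij) d_ij`
#' where `v+`/`v-` are the total positive/negative weight, `e_ij` is the
#' configuration-model expectation `s_i s_j / v` within each sign layer,
#' `d_ij` indicates co-membership, and the resolution `gamma` multiplies the
#' expected-weight terms. Sums run over all ordered pairs; the diagonal is
#' removed first (its null term is partition-independent).
#'
#' @param W symmetric signed weight matrix.
#' @param membership integer module labels, one per node.
#' @param gamma resolution parameter.
#' @return the scalar Q.
#' @export
signedModularity <- function(W, membership, gamma = 1) {
  W <- asSignedGraph(W)
  stopifnot(length(membership) == nrow(W))
  cpp_signed_modularity(W, as.integer(as.integer(factor(membership))), gamma)
}

#' One seeded Louvain run on a signed graph
#'
#' Greedy two-phase Louvain (local moving + aggregation) maximising the
#' signed modularity of [signedModularity()]. Node order is randomised by a
#' deterministic internal RNG, so a fixed seed reproduces the partition
#' exactly; ties are broken toward the lowest community index.
#'
#' @inheritParams signedModularity
#' @param seed integer seed.
#' @return integer membership vector (contiguous ids, 1-based).
#' @export
louvainOnce <- function(W, gamma = 1, seed = 1L) {
  W <- asSignedGraph(W)
  cpp_louvain(W, gamma, as.integer(seed))
}

#' Consensus partition over repeated Louvain runs
#'
#' Runs the seeded Louvain `nReps` times, forms the module co-assignment
#' (agreement) matrix, thresholds it at its mean off-diagonal value, and
#' re-clusters the thresholded agreement graph; this is iterated until all
#' runs coincide. If the agreement graph degenerates or the iteration does
#' not converge, the best-Q individual run is returned.
#'
#' @inheritParams louvainOnce
#' @param nReps number of Louvain repetitions (default 500).
#' @param maxIter maximum consensus iterations.
#' @return list with `membership`, `Q` (on the input graph) and `nModules`.
#' @export
consensusPartition <- function(W, gamma = 1, nReps = 500L, seed = 1L,
                               maxIter = 50L) {
  stopifnot(nReps >= 1L)
  W <- asSignedGraph(W)
  cpp_consensus(W, gamma, as.integer(nReps), as.integer(seed),
                as.integer(maxIter))
}

#' Resolution (gamma) sweep with partition-stability scoring
#'
#' For each gamma on the grid, `nIter` seeded Louvain runs are scored by the
#' mean pairwise normalized mutual information among the resulting
#' partitions; the recommended gamma is the stability argmax (ties resolve
#' to the smallest gamma).
#'
#' @inheritParams louvainOnce
#' @param lo,hi,step grid of gamma values.
#' @param nIter Louvain runs per gamma (default 100).
#' @return list with `gamma` (recommended) and `table` (data.frame: gamma,
#'   stability, median module count).
#' @export
gammaSweep <- function(W, lo = 0.5, hi = 2.5, step = 0.1, nIter = 100L,
                       seed = 1L) {
  stopifnot(lo < hi)
  W <- asSignedGraph(W)
  gammas <- seq(lo, hi, by = step)
  stab <- numeric(length(gammas)); nmod <- numeric(length(gammas))
  for (gi in seq_along(gammas)) {
    parts <- lapply(seq_len(nIter), function(r)
      cpp_louvain(W, gammas[gi], deriveSeed(seed, sprintf("g%0.3f-%d",
                                                          gammas[gi], r))))
    if (nIter == 1L) {
      stab[gi] <- 1
    } else {
      acc <- 0; npair <- 0
      for (i in seq_len(nIter - 1L))
        for (j in (i + 1L):nIter) {
          acc <- acc + nmi(parts[[i]], parts[[j]])
          npair <- npair + 1
        }
      stab[gi] <- acc / npair
    }
    nmod[gi] <- median(vapply(parts, max, numeric(1)))
  }
  best <- which(stab >= max(stab) - 1e-12)[1]
  list(gamma = gammas[best],
       table = data.frame(gamma = gammas, stability = stab,
                          medianModules = nmod))
}

#' Per-window community detection on an MTD tensor
#'
#' Applies [consensusPartition()] to each window's signed coupling graph
#' (self-coupling removed), yielding the time-resolved module assignments
#' `Ci_T`, modularity `Q_T` and module counts. Window-level seeds are
#' derived deterministically from `seed`.
#'
#' @param tensor an [MTDTensor-class].
#' @param gamma resolution parameter (default 1.1, the value at which the
#'   sweep of [gammaSweep()] is most stable on data of this kind).
#' @param nReps consensus repetitions per window (default 500).
#' @param seed integer seed.
#' @return a [WindowPartitionSet-class].
#' @export
runWindows <- function(tensor, gamma = 1.1, nReps = 500L, seed = 1L) {
  stopifnot(is(tensor, "MTDTensor"))
  nw <- nWindows(tensor)
  seeds <- vapply(seq_len(nw), function(k)
    deriveSeed(seed, sprintf("window-%d", k)), integer(1))
  res <- cpp_consensus_batch(tensor@coupling, gamma, as.integer(nReps),
                             seeds, 50L)
  new("WindowPartitionSet", assignments = res$assignments, Q = res$Q,
      nModules = res$n_modules,
      gamma = gamma, matched = FALSE, regionLabels = regionLabels(tensor))
}
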