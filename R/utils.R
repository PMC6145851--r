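#' @useDynLib netdyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats coef cor lm median pf pnorm pt quantile rnorm sd var
#' @importFrom utils read.table write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards, so generators are pure functions of their seed.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stage seed from a master seed and a label, staying below 2^31.
# Doubles are exact here because all intermediates stay below 2^53.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563 + 1)
}

# Population standard deviation (divides by n, not n - 1).
popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Pearson (non-excess) kurtosis: fourth standardised moment m4 / m2^2.
pearsonKurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) stop("kurtosis undefined for a constant series")
  mean((x - mean(x))^4) / m2^2
}

#' Normalized mutual information between two partitions
#'
#' Measures the agreement of two module assignments of the same nodes,
#' normalized as `2 I(X;Y) / (H(X) + H(Y))` so that identical groupings give
#' 1 and independent groupings give values near 0. Two all-in-one-module
#' partitions (both entropies zero) are defined to agree perfectly.
#'
#' @param a,b integer vectors of module labels (same length).
#' @return a scalar in \[0, 1\].
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  ja <- as.integer(factor(a)); jb <- as.integer(factor(b))
  n <- length(ja)
  tab <- table(ja, jb) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / (pa[row(tab)[nz]] * pb[col(tab)[nz]])))
  2 * mi / (ha + hb)
}

# Canonical double-gamma haemodynamic response kernel sampled at `tr`
# seconds, covering `duration` seconds, normalised to unit sum. Peaks at 6 s
# with an undershoot peaking at 16 s scaled by 1/6.
hrfKernel <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

# Hungarian (potentials + shortest augmenting path) minimum-cost assignment
# for a square cost matrix; returns for each row its assigned column. O(n^3).
# Arrays are padded by one slot so that "column 0" is the virtual start.
hungarianAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)       # row potentials, u[i + 1]
  v <- numeric(n + 1L)       # column potentials, v[j + 1]
  p <- integer(n + 1L)       # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) ans[p[j + 1L]] <- j
  ans
}
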