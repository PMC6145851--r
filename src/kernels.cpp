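#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic, platform-independent RNG (xorshift64*) so that seeded
// community detection reproduces bit-for-bit across machines.
struct XRng {
  uint64_t s;
  explicit XRng(uint32_t seed) : s(seed ? (uint64_t)seed * 2685821657736338717ULL
                                        : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform on [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer on [0, n)
  int uint(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

static void shuffle_idx(std::vector<int>& v, XRng& rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rng.uint(i + 1);
    std::swap(v[i], v[j]);
  }
}

// ---------------------------------------------------------------------------
// MTD: sliding-window mean of products of standardised temporal derivatives.
// D is the (T-1) x N matrix of derivatives already divided by their
// per-region sd; windows of length w slide with the given stride and only
// full windows are emitted.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_mtd(const NumericMatrix& D, int w, int stride) {
  const int Td = D.nrow(), N = D.ncol();
  if (w < 1 || w > Td) stop("window length out of range");
  const int nw = (Td - w) / stride + 1;
  NumericVector out(Dimension(N, N, nw));
  std::vector<double> S(N * N, 0.0);

  if (stride == 1) {
    // incremental rank-one updates
    for (int t = 0; t < w; ++t)
      for (int j = 0; j < N; ++j) {
        const double dj = D(t, j);
        if (dj == 0.0) continue;
        for (int i = 0; i < N; ++i) S[i + j * N] += D(t, i) * dj;
      }
    for (int k = 0; k < nw; ++k) {
      double* ok = &out[(size_t)k * N * N];
      for (int q = 0; q < N * N; ++q) ok[q] = S[q] / w;
      if (k + 1 < nw) {
        const int t_old = k, t_new = k + w;
        for (int j = 0; j < N; ++j) {
          const double djo = D(t_old, j), djn = D(t_new, j);
          for (int i = 0; i < N; ++i)
            S[i + j * N] += D(t_new, i) * djn - D(t_old, i) * djo;
        }
      }
    }
  } else {
    for (int k = 0; k < nw; ++k) {
      std::fill(S.begin(), S.end(), 0.0);
      const int t0 = k * stride;
      for (int t = t0; t < t0 + w; ++t)
        for (int j = 0; j < N; ++j) {
          const double dj = D(t, j);
          if (dj == 0.0) continue;
          for (int i = 0; i < N; ++i) S[i + j * N] += D(t, i) * dj;
        }
      double* ok = &out[(size_t)k * N * N];
      for (int q = 0; q < N * N; ++q) ok[q] = S[q] / w;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Signed modularity. The quality of a partition of a signed weighted graph:
//   Q = (1/v+) sum_ij (w+_ij - g e+_ij) d_ij  -  (1/(v+ + v-)) sum_ij (w-_ij - g e-_ij) d_ij
// with e+-_ij = s_i s_j / v within each sign layer and the resolution g
// multiplying the expected-weight terms. The sum runs over all ordered
// pairs including the (partition-independent) diagonal, so the diagonal of
// the input should be zero.
// ---------------------------------------------------------------------------
static std::vector<double> modularity_matrix(const NumericMatrix& W, double gamma,
                                             double* vplus_out) {
  const int N = W.nrow();
  std::vector<double> sp(N, 0.0), sn(N, 0.0);
  double vp = 0.0, vn = 0.0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      const double x = W(i, j);
      if (x > 0)      { sp[i] += x;  vp += x; }
      else if (x < 0) { sn[i] -= x;  vn -= x; }
    }
  if (vplus_out) *vplus_out = vp;
  std::vector<double> B((size_t)N * N, 0.0);
  const double fp = vp > 0 ? 1.0 / vp : 0.0;
  const double fm = (vp + vn) > 0 ? 1.0 / (vp + vn) : 0.0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      const double x = W(i, j);
      const double wp = x > 0 ? x : 0.0;
      const double wn = x < 0 ? -x : 0.0;
      double b = 0.0;
      if (vp > 0) b += fp * (wp - gamma * sp[i] * sp[j] / vp);
      if (vn > 0) b -= fm * (wn - gamma * sn[i] * sn[j] / vn);
      B[(size_t)i + (size_t)j * N] = b;
    }
  // symmetrise to guard against tiny asymmetries in the input
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < j; ++i) {
      const double m = 0.5 * (B[(size_t)i + (size_t)j * N] + B[(size_t)j + (size_t)i * N]);
      B[(size_t)i + (size_t)j * N] = m;
      B[(size_t)j + (size_t)i * N] = m;
    }
  return B;
}

// [[Rcpp::export]]
double cpp_signed_modularity(const NumericMatrix& W, const IntegerVector& comm,
                             double gamma) {
  const int N = W.nrow();
  double vp = 0.0;
  std::vector<double> B = modularity_matrix(W, gamma, &vp);
  if (vp <= 0) stop("modularity undefined: graph has no positive weight");
  double Q = 0.0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (comm[i] == comm[j]) Q += B[(size_t)i + (size_t)j * N];
  return Q;
}

// Louvain local-moving + aggregation on a (generalised) modularity matrix.
// Tie-breaks: a move requires a strictly positive gain (> 1e-13); among
// equal-gain candidates the lowest community index wins.
static void louvain_on_B(std::vector<double>& B, int N, XRng& rng,
                         std::vector<int>& membership) {
  std::vector<int> node2comm(N);
  for (int i = 0; i < N; ++i) node2comm[i] = i;  // current level communities
  std::vector<int> orig(N);                       // original node -> community
  for (int i = 0; i < N; ++i) orig[i] = i;
  int n = N;

  for (int level = 0; level < 64; ++level) {
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;

    bool any_move = false;
    bool improved = true;
    int sweeps = 0;
    std::vector<double> link(n, 0.0);
    while (improved && sweeps < 256) {
      improved = false;
      ++sweeps;
      shuffle_idx(order, rng);
      for (int oi = 0; oi < n; ++oi) {
        const int i = order[oi];
        const int ci = comm[i];
        // connection of i to each community under B (excluding self-term)
        std::fill(link.begin(), link.end(), 0.0);
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          link[comm[j]] += B[(size_t)i + (size_t)j * n];
        }
        double best_gain = 1e-13;
        int best_c = ci;
        for (int c = 0; c < n; ++c) {
          if (c == ci) continue;
          // gain of moving i from ci to c (factor 2 from symmetry; constant
          // diagonal term cancels)
          const double g = 2.0 * (link[c] - link[ci]);
          if (g > best_gain + 1e-15 ||
              (std::abs(g - best_gain) <= 1e-15 && best_c != ci && c < best_c)) {
            if (g > 1e-13) { best_gain = g; best_c = c; }
          }
        }
        if (best_c != ci) {
          comm[i] = best_c;
          improved = true;
          any_move = true;
        }
      }
    }

    // renumber communities contiguously (by lowest member index)
    std::vector<int> remap(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (remap[comm[i]] < 0) remap[comm[i]] = nc++;
    for (int i = 0; i < n; ++i) comm[i] = remap[comm[i]];

    // update original-node membership
    for (int v = 0; v < N; ++v) orig[v] = comm[orig[v]];

    if (!any_move || nc == n) break;

    // aggregate B
    std::vector<double> B2((size_t)nc * nc, 0.0);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        B2[(size_t)comm[i] + (size_t)comm[j] * nc] += B[(size_t)i + (size_t)j * n];
    B.swap(B2);
    n = nc;
  }

  // final renumbering by first appearance over original node order
  std::vector<int> remap(N, -1);
  int nc = 0;
  membership.assign(N, 0);
  for (int v = 0; v < N; ++v) {
    if (remap[orig[v]] < 0) remap[orig[v]] = ++nc;  // 1-based
    membership[v] = remap[orig[v]];
  }
}

// [[Rcpp::export]]
IntegerVector cpp_louvain(const NumericMatrix& W, double gamma, int seed) {
  const int N = W.nrow();
  double vp = 0.0;
  std::vector<double> B = modularity_matrix(W, gamma, &vp);
  if (vp <= 0) stop("modularity undefined: graph has no positive weight");
  XRng rng((uint32_t)seed);
  std::vector<int> memb;
  louvain_on_B(B, N, rng, memb);
  return IntegerVector(memb.begin(), memb.end());
}

// Deterministic local-moving refinement ("fine-tuning") of a partition on
// the modularity matrix: sweep nodes in index order, moving each to the
// community (including a fresh singleton) with the best positive gain,
// until a full sweep makes no move. Never lowers Q.
static void refine_partition(const std::vector<double>& B, int N,
                             std::vector<int>& memb) {
  int M = 0;
  for (int i = 0; i < N; ++i) M = std::max(M, memb[i]);
  std::vector<double> link((size_t)M + 2, 0.0);
  for (int sweep = 0; sweep < 256; ++sweep) {
    bool moved = false;
    for (int i = 0; i < N; ++i) {
      std::fill(link.begin(), link.end(), 0.0);
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        link[memb[j]] += B[(size_t)i + (size_t)j * N];
      }
      const int ci = memb[i];
      double best_gain = 1e-13;
      int best_c = ci;
      for (int c = 1; c <= M + 1; ++c) {  // M + 1 = empty community
        if (c == ci) continue;
        const double g = 2.0 * (link[c] - link[ci]);
        if (g > best_gain + 1e-15) { best_gain = g; best_c = c; }
      }
      if (best_c != ci) {
        memb[i] = best_c;
        if (best_c == M + 1) { ++M; link.resize((size_t)M + 2, 0.0); }
        moved = true;
      }
    }
    if (!moved) break;
  }
  // renumber contiguously by first appearance
  std::vector<int> remap((size_t)M + 1, 0);
  int nc = 0;
  for (int i = 0; i < N; ++i) {
    if (remap[memb[i]] == 0) remap[memb[i]] = ++nc;
    memb[i] = remap[memb[i]];
  }
}

static double Q_of(const std::vector<double>& B, int N, const std::vector<int>& m) {
  double Q = 0.0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (m[i] == m[j]) Q += B[(size_t)i + (size_t)j * N];
  return Q;
}

// Consensus clustering: run the seeded Louvain n_reps times, build the module
// co-assignment (agreement) matrix, threshold it at the mean off-diagonal
// agreement and re-cluster the thresholded agreement graph; iterate until all
// runs coincide. Returns the consensus partition and its Q on the input graph.
static List consensus_impl(const NumericMatrix& W, double gamma, int n_reps,
                           int seed, int max_iter) {
  const int N = W.nrow();
  double vp = 0.0;
  std::vector<double> B = modularity_matrix(W, gamma, &vp);
  if (vp <= 0) stop("modularity undefined: graph has no positive weight");
  XRng rng((uint32_t)seed);

  std::vector<std::vector<int> > parts((size_t)n_reps);
  for (int r = 0; r < n_reps; ++r) {
    std::vector<double> Bc(B);
    louvain_on_B(Bc, N, rng, parts[r]);
  }

  std::vector<int> consensus = parts[0];
  for (int iter = 0; iter < max_iter; ++iter) {
    bool all_same = true;
    for (int r = 1; r < n_reps && all_same; ++r)
      if (parts[r] != parts[0]) all_same = false;
    if (all_same) { consensus = parts[0]; break; }

    // agreement matrix
    std::vector<double> A((size_t)N * N, 0.0);
    for (int r = 0; r < n_reps; ++r)
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i)
          if (parts[r][i] == parts[r][j]) A[(size_t)i + (size_t)j * N] += 1.0;
    double off = 0.0;
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        A[(size_t)i + (size_t)j * N] /= n_reps;
        if (i != j) off += A[(size_t)i + (size_t)j * N];
      }
    const double tau = N > 1 ? off / ((double)N * (N - 1)) : 0.0;
    NumericMatrix At(N, N);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        At(i, j) = (i != j && A[(size_t)i + (size_t)j * N] >= tau)
                       ? A[(size_t)i + (size_t)j * N] : 0.0;

    double vpa = 0.0;
    std::vector<double> BA = modularity_matrix(At, 1.0, &vpa);
    if (vpa <= 0) {  // no agreement above threshold: fall back to best run
      double bestQ = -1e300;
      for (int r = 0; r < n_reps; ++r) {
        const double q = Q_of(B, N, parts[r]);
        if (q > bestQ) { bestQ = q; consensus = parts[r]; }
      }
      break;
    }
    for (int r = 0; r < n_reps; ++r) {
      std::vector<double> Bc(BA);
      louvain_on_B(Bc, N, rng, parts[r]);
    }
    consensus = parts[0];
    if (iter == max_iter - 1) {  // did not converge: best-Q run on original
      double bestQ = -1e300;
      for (int r = 0; r < n_reps; ++r) {
        const double q = Q_of(B, N, parts[r]);
        if (q > bestQ) { bestQ = q; consensus = parts[r]; }
      }
    }
  }

  refine_partition(B, N, consensus);
  const double Q = Q_of(B, N, consensus);
  int nmod = 0;
  for (int i = 0; i < N; ++i) nmod = std::max(nmod, consensus[i]);
  return List::create(_["membership"] = IntegerVector(consensus.begin(), consensus.end()),
                      _["Q"] = Q, _["n_modules"] = nmod);
}

// [[Rcpp::export]]
List cpp_consensus(const NumericMatrix& W, double gamma, int n_reps, int seed,
                   int max_iter) {
  return consensus_impl(W, gamma, n_reps, seed, max_iter);
}

// ---------------------------------------------------------------------------
// Per-window cartography: participation coefficient (positive weights) and
// module-degree z-score (positive weights, population sd within module).
// The diagonal is ignored.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_topology(const NumericMatrix& W, const IntegerVector& comm) {
  const int N = W.nrow();
  int M = 0;
  for (int i = 0; i < N; ++i) M = std::max(M, comm[i]);
  NumericVector Bv(N), Wz(N);
  std::vector<double> ks((size_t)N * M, 0.0);  // node x module positive strength
  std::vector<double> ktot(N, 0.0);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      if (i == j) continue;
      const double x = W(i, j);
      if (x > 0) {
        ks[(size_t)i + (size_t)(comm[j] - 1) * N] += x;
        ktot[i] += x;
      }
    }
  for (int i = 0; i < N; ++i) {
    if (ktot[i] <= 0) { Bv[i] = 0.0; continue; }
    double acc = 0.0;
    for (int s = 0; s < M; ++s) {
      const double f = ks[(size_t)i + (size_t)s * N] / ktot[i];
      acc += f * f;
    }
    Bv[i] = 1.0 - acc;
  }
  // within-module strength kappa and per-module z-score
  std::vector<double> kap(N), mu(M, 0.0), s2(M, 0.0);
  std::vector<int> cnt(M, 0);
  for (int i = 0; i < N; ++i) {
    kap[i] = ks[(size_t)i + (size_t)(comm[i] - 1) * N];
    mu[comm[i] - 1] += kap[i];
    cnt[comm[i] - 1] += 1;
  }
  for (int s = 0; s < M; ++s) if (cnt[s] > 0) mu[s] /= cnt[s];
  for (int i = 0; i < N; ++i) {
    const double d = kap[i] - mu[comm[i] - 1];
    s2[comm[i] - 1] += d * d;
  }
  for (int s = 0; s < M; ++s) if (cnt[s] > 0) s2[s] = std::sqrt(s2[s] / cnt[s]);
  for (int i = 0; i < N; ++i) {
    const double sd = s2[comm[i] - 1];
    Wz[i] = sd > 0 ? (kap[i] - mu[comm[i] - 1]) / sd : 0.0;
  }
  return List::create(_["B"] = Bv, _["W"] = Wz);
}

// Fused fast path for surrogate-null testing: standardised derivative matrix
// in, per-window mean participation coefficient out, under a fixed partition.
// Equals mean(participation(window graph)) over the sliding MTD windows.
// [[Rcpp::export]]
NumericVector cpp_mean_participation_series(const NumericMatrix& D, int w,
                                            const IntegerVector& comm) {
  const int Td = D.nrow(), N = D.ncol();
  if (w < 1 || w > Td) stop("window length out of range");
  int M = 0;
  for (int i = 0; i < N; ++i) M = std::max(M, comm[i]);
  const int nw = Td - w + 1;
  NumericVector out(nw);
  std::vector<double> S((size_t)N * N, 0.0);
  for (int t = 0; t < w; ++t)
    for (int j = 0; j < N; ++j) {
      const double dj = D(t, j);
      for (int i = 0; i < N; ++i) S[(size_t)i + (size_t)j * N] += D(t, i) * dj;
    }
  std::vector<double> ks((size_t)N * M);
  for (int k = 0; k < nw; ++k) {
    std::fill(ks.begin(), ks.end(), 0.0);
    std::vector<double> ktot(N, 0.0);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        if (i == j) continue;
        const double x = S[(size_t)i + (size_t)j * N] / w;
        if (x > 0) {
          ks[(size_t)i + (size_t)(comm[j] - 1) * N] += x;
          ktot[i] += x;
        }
      }
    double meanB = 0.0;
    for (int i = 0; i < N; ++i) {
      double b = 0.0;
      if (ktot[i] > 0) {
        double acc = 0.0;
        for (int s = 0; s < M; ++s) {
          const double f = ks[(size_t)i + (size_t)s * N] / ktot[i];
          acc += f * f;
        }
        b = 1.0 - acc;
      }
      meanB += b;
    }
    out[k] = meanB / N;
    if (k + 1 < nw) {
      const int t_old = k, t_new = k + w;
      for (int j = 0; j < N; ++j) {
        const double djo = D(t_old, j), djn = D(t_new, j);
        for (int i = 0; i < N; ++i)
          S[(size_t)i + (size_t)j * N] += D(t_new, i) * djn - D(t_old, i) * djo;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Batched per-window kernels: one call per run instead of one per window,
// keeping the per-window R overhead out of simulation studies.
// ---------------------------------------------------------------------------

static List consensus_impl(const NumericMatrix& W, double gamma, int n_reps,
                           int seed, int max_iter);

// [[Rcpp::export]]
List cpp_consensus_batch(const NumericVector& tensor, double gamma,
                         int n_reps, const IntegerVector& seeds,
                         int max_iter) {
  IntegerVector dims = tensor.attr("dim");
  const int N = dims[0], nw = dims[2];
  if (seeds.size() != nw) stop("one seed per window required");
  IntegerMatrix assign(nw, N);
  NumericVector Q(nw);
  IntegerVector nmod(nw);
  NumericMatrix W(N, N);
  for (int k = 0; k < nw; ++k) {
    const double* src = &tensor[(size_t)k * N * N];
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        W(i, j) = (i == j) ? 0.0 : src[i + j * N];
    List res = consensus_impl(W, gamma, n_reps, seeds[k], max_iter);
    IntegerVector m = res["membership"];
    for (int i = 0; i < N; ++i) assign(k, i) = m[i];
    Q[k] = as<double>(res["Q"]);
    nmod[k] = as<int>(res["n_modules"]);
  }
  return List::create(_["assignments"] = assign, _["Q"] = Q,
                      _["n_modules"] = nmod);
}

// [[Rcpp::export]]
List cpp_topology_batch(const NumericVector& tensor,
                        const IntegerMatrix& assign) {
  IntegerVector dims = tensor.attr("dim");
  const int N = dims[0], nw = dims[2];
  if (assign.nrow() != nw || assign.ncol() != N)
    stop("assignment shape mismatch");
  NumericMatrix B(nw, N), Wz(nw, N);
  NumericMatrix Wk(N, N);
  IntegerVector comm(N);
  for (int k = 0; k < nw; ++k) {
    const double* src = &tensor[(size_t)k * N * N];
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        Wk(i, j) = (i == j) ? 0.0 : src[i + j * N];
    for (int i = 0; i < N; ++i) comm[i] = assign(k, i);
    List res = cpp_topology(Wk, comm);
    NumericVector b = res["B"], w = res["W"];
    for (int i = 0; i < N; ++i) { B(k, i) = b[i]; Wz(k, i) = w[i]; }
  }
  return List::create(_["B"] = B, _["W"] = Wz);
}

// VAR recursion over pre-drawn innovations: E is (T x d x S) flattened,
// coefs d x d x p; returns the (T - burn) x d x S array of states.
// [[Rcpp::export]]
NumericVector cpp_var_recursion(const NumericVector& E, const NumericVector& coefs,
                                int d, int p, int S, int Ttot, int burn) {
  NumericVector out(Dimension(Ttot - burn, d, S));
  const double* Ep = &E[0];
  const double* Cp = &coefs[0];
  double* Op = &out[0];
  // contiguous working buffer: time-major (d x Ttot) per surrogate
  std::vector<double> X((size_t)d * Ttot);
  for (int s = 0; s < S; ++s) {
    const double* Es = Ep + (size_t)s * Ttot * d;
    for (int i = 0; i < d; ++i)
      for (int t = 0; t < Ttot; ++t)
        X[(size_t)t * d + i] = Es[(size_t)t + (size_t)i * Ttot];
    for (int t = 0; t < Ttot; ++t) {
      double* xt = &X[(size_t)t * d];
      const int lmax = t < p ? t : p;
      for (int l = 1; l <= lmax; ++l) {
        const double* xl = &X[(size_t)(t - l) * d];
        const double* A = Cp + (size_t)(l - 1) * d * d;
        for (int j = 0; j < d; ++j) {
          const double hj = xl[j];
          const double* Aj = A + (size_t)j * d;
          for (int i = 0; i < d; ++i) xt[i] += Aj[i] * hj;
        }
      }
    }
    double* Os = Op + (size_t)s * (Ttot - burn) * d;
    for (int t = burn; t < Ttot; ++t)
      for (int i = 0; i < d; ++i)
        Os[(size_t)(t - burn) + (size_t)i * (Ttot - burn)] = X[(size_t)t * d + i];
  }
  return out;
}

// Batched fused mean-participation: D is (Td x N x S) standardised
// derivatives; returns (Td - w + 1) x S matrix of per-window mean B.
// [[Rcpp::export]]
NumericMatrix cpp_mean_participation_batch(const NumericVector& D, int w,
                                           const IntegerVector& comm,
                                           int Td, int N, int S) {
  NumericMatrix out(Td - w + 1, S);
  NumericMatrix Ds(Td, N);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < N; ++j)
      for (int t = 0; t < Td; ++t)
        Ds(t, j) = D[(size_t)t + (size_t)j * Td + (size_t)s * Td * N];
    NumericVector r = cpp_mean_participation_series(Ds, w, comm);
    for (int k = 0; k < r.size(); ++k) out(k, s) = r[k];
  }
  return out;
}

// Causal IIR filtering (direct form, zero initial conditions) down each
// column: y_t = sum_k b_k x_{t-k} - sum_m a_m y_{t-m}, a_0 assumed 1 after
// normalisation by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_iir(const NumericVector& b, const NumericVector& a,
                      const NumericMatrix& X) {
  const int T = X.nrow(), C = X.ncol();
  const int nb = b.size(), na = a.size();
  NumericMatrix Y(T, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X[(size_t)c * T];
    double* y = &Y[(size_t)c * T];
    for (int t = 0; t < T; ++t) {
      double acc = 0.0;
      const int kb = t + 1 < nb ? t + 1 : nb;
      for (int k = 0; k < kb; ++k) acc += b[k] * x[t - k];
      const int ka = t + 1 < na ? t + 1 : na;
      for (int m = 1; m < ka; ++m) acc -= a[m] * y[t - m];
      y[t] = acc;
    }
  }
  return Y;
}
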