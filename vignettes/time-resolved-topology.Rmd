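---
title: "Time-resolved network topology of parcellated BOLD data: models and methods"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Time-resolved network topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(netdyn)
```

# Overview

`netdyn` estimates how the community structure of a functional brain network
reorganises over time, and tests whether that reorganisation differs across
pharmacological or cognitive conditions. The pipeline is

1. parcellated BOLD time series (frames x regions), optionally band-passed
   and motion-screened;
2. time-resolved coupling via the multiplication of temporal derivatives
   (MTD) over a sliding window;
3. per-window community detection on the signed weighted coupling graph
   (Louvain with consensus clustering);
4. regional cartography per window — participation coefficient $B_T$
   (between-module connectivity) and module-degree z-score $W_T$
   (within-module connectivity) — pooled into a 2-D occupancy histogram,
   the *cartographic profile*;
5. regional flexibility (module switching across Hungarian-matched window
   labels);
6. inference: stationary VAR surrogate nulls for dynamism, per-bin 2x2
   crossover ANOVA with FDR, pupil-coupling mixed models, windowed task
   GLMs, and permutation/bootstrap correlation comparisons.

Because suitable public data with ground truth do not exist at desk scale,
the package ships a first-class synthetic generator whose outputs carry the
planted module structure and the latent integration series, so every stage
can be validated against a known truth.

# The coupling estimator

For regions $i,j$ and window length $w$ (default 15 frames, about 33 s at a
repetition time of 2.2 s),
$$\mathrm{MTD}_{ijt} = \frac{1}{w}\sum_{t-w/2}^{t+w/2}
  \frac{dt_{it}\, dt_{jt}}{\sigma_{i}\,\sigma_{j}},$$
where $dt$ is the backward first difference of the region's series and
$\sigma$ is the (population) standard deviation of the *full-run*
derivative, i.e. the per-region normalisation sits outside the window sum.
Implementation choices that the estimator's definition leaves open:

* **Window alignment.** Windows are "valid" only: the first window covers
  derivative samples $1..w$, so a run of $T$ frames yields $(T-1)-w+1$
  windows at stride 1. Derivative sample $t$ sits between frames $t$ and
  $t+1$; frame-level covariates are aligned to a window by averaging over
  frames $k..k+w$ (`windowAverage()`).
* **Stride.** Exposed, default 1 (every window).
* A constant region has $\sigma = 0$ and no coupling scale; this is an
  error naming the region rather than a silent NaN.

The windowed mean of standardised derivative products converges, over a
long stationary run, to the Pearson correlation of the derivative series;
the tests assert this on $T = 5000$ simulations.

# Signed community structure

Each window's coupling matrix is an unthresholded signed weighted graph.
Partition quality is the asymmetric signed modularity
$$Q = \frac{1}{v^+}\sum_{ij}\left(w^+_{ij}-\gamma e^+_{ij}\right)
      \delta_{M_iM_j}
    - \frac{1}{v^++v^-}\sum_{ij}\left(w^-_{ij}-\gamma e^-_{ij}\right)
      \delta_{M_iM_j},$$
with $e^\pm_{ij} = s^\pm_i s^\pm_j / v^\pm$ the configuration-model
expectation within each sign layer. Two conventions deserve note because
the formula alone does not fix them:

* **Resolution.** $\gamma$ multiplies the expected-weight terms — the
  standard signed-modularity convention, and the only placement under which
  a resolution sweep is meaningful. Default $\gamma = 1.1$.
* **Diagonal.** Self-coupling is removed before community detection (its
  null term is partition-independent, so this only shifts $Q$ by a
  constant).

`louvainOnce()` is a two-phase greedy Louvain on the generalised modularity
matrix $B_{ij}$; node order is randomised by a deterministic internal RNG
(so a seed reproduces partitions bit-for-bit across platforms), moves
require a strictly positive gain, and ties break toward the lowest
community index. `consensusPartition()` (default 500 repetitions per
window) forms the module co-assignment matrix across repetitions,
thresholds it at its mean off-diagonal value, re-clusters, iterates to
unanimity, and finally applies a deterministic local-moving fine-tuning
pass on the original graph, which can only raise $Q$. On graphs with no
community structure at all the consensus can still land marginally below
the median individual run — the tests document this expressly rather than
hiding it.

`gammaSweep()` scores each $\gamma$ on a 0.5–2.5 grid (step 0.1, 100
Louvain runs) by the mean pairwise normalized mutual information (NMI,
normalised by the mean entropy) among the runs. Pairwise-mean NMI (rather
than NMI against a reference) is used; note its known bias: at high
resolution even structureless graphs fragment *consistently*, inflating
stability, so the sweep should be read jointly with the module counts the
table reports.

# Cartography, profiles, flexibility

Per window and region, with $\kappa$ the strength of *positive*
connections:
$$W_{iT} = \frac{\kappa_{iT}-\bar\kappa_{s_iT}}{\sigma_{\kappa_{s_iT}}},
\qquad
B_{iT} = 1-\sum_{s=1}^{n_M}\left(\frac{\kappa_{isT}}{\kappa_{iT}}\right)^2.$$
$B$ is 0 when all positive links stay within the region's own module and
approaches $1 - 1/n_M$ for a uniform spread. Choices:

* $\kappa$ uses positive weights only in *both* measures (the definition of
  $B$ is explicit about this; for $W$ it is a choice, switchable via
  `weights = "signed"`).
* Module z-scoring uses the population standard deviation; a module whose
  members all have equal within-strength assigns $W = 0$.
* Isolated regions ($\kappa_i = 0$) score $B = 0$.

The cartographic profile pools all region x window $(B, W)$ samples into a
fixed histogram (defaults 100 x 100 bins, $B \in [0,1]$,
$W \in [-5,5]$; group analyses in this package use 20 x 20 for
tractability). $W$ samples outside the range are clipped into the edge bins
and counted, never dropped silently.

Module labels from independent windows are arbitrary, so flexibility first
chains a Hungarian maximum-overlap matching forward through time
(window $t$ against the already-matched window $t-1$; unmatched new modules
get fresh ids). Flexibility is then the fraction of transitions at which a
region's matched label changes. The printed normalisation "to the total
number of modules" is ambiguous, so both variants ship:
`switch_fraction` (default) and `per_module` (divided by the mean module
count); the variant tag travels with the output.

# Stationary surrogate nulls

`fitVar()` fits a VAR($p$) (default order 6, matching the temporal extent
of the haemodynamic response at TR ~2 s) by stacked least squares on
demeaned runs, then stores a linear transform under which simulated
surrogates have *exactly* the empirical covariance of the training data —
reconciling coefficient fitting with covariance matching. Stability is
checked via the companion-matrix spectral radius; unstable fits are errors
reporting the radius, not silently shrunk. When regions exceed
`subspaceDim` (default 50) the fit runs in the top principal subspace and
is projected back, with per-region white noise restoring truncated
variance; this is reported loudly because it changes the null's fine
structure.

`simulateVar()` draws Gaussian innovations, discards a burn-in, and by
default passes surrogates through the same 0.01–0.125 Hz zero-phase
band-pass as the analysis path. The dynamism statistic is the Pearson
kurtosis (plain fourth standardised moment) of either the window-to-window
*difference* of the mean-$B_T$ series (default, the preregistered-style
variant) or its *level*; the observation is significant when it exceeds
the null's 95th percentile. Both variants are computed; neither is
silently preferred.

At calibration scale, scoring thousands of surrogates through per-window
Louvain is wasteful and unnecessary: the statistic map must only be
*identical* for observation and surrogates. `meanParticipationSeries()`
therefore evaluates mean $B_T$ under a single fixed partition (the
consensus partition of the observed run's time-averaged graph), and the
tests verify it equals the staged tensor computation to machine precision.

# Group statistics

* **Crossover ANOVA** (`binAnova2x2()`): per profile bin, a fully
  within-subject 2 (pre/post) x 2 (drug/placebo) ANOVA of occupancy; the
  interaction F is computed from the sums-of-squares decomposition and
  equals the squared paired $t$ of the per-subject interaction contrast
  (asserted to 1e-9 in tests). FDR across bins at $q \le 0.05$ via the
  Benjamini–Hochberg step-up.
* **Pupil coupling** (`pupilTopologyCorrelation()`): the frame-rate pupil
  trace (artifact-interpolated with shape-preserving cubics, 5 Hz
  low-passed, z-scored, averaged within TRs; subjects with over half their
  samples interpolated are flagged for exclusion) is convolved with a
  canonical double-gamma kernel, window-averaged, and Spearman-correlated
  with each bin's occupancy series. Group inference fits
  `z ~ 0 + bin + (1 | subject)` on Fisher-z correlations with Satterthwaite
  tests, FDR across bins. The subject random intercept is shared across
  bins, which is what makes a per-subject-per-bin single observation
  identifiable.
* **Task GLM** (`taskGlm()`): condition boxcars, optionally convolved with
  the double-gamma kernel, averaged onto the window grid; OLS per unit;
  two single-degree F contrasts on the 0/1/2/3-back betas — the main
  effect (mean of 1–3-back vs 0-back) and the load effect (linear trend).
  The window/haemodynamic offset is a knob (`windowOffset`, default 0).
* **Correlation comparisons**: seeded permutation test (two-sided,
  add-one), percentile bootstrap CI, and a Fisher-z Dunn–Clark test which
  reduces to the independent-samples z when the cross-dataset dependency
  `rCross` is left at 0 (the dependency structure between two different
  cohorts measured on the same parcellation is not identifiable from the
  summary statistics alone, so it is an explicit argument rather than a
  hidden assumption).

# The synthetic generator

Frames are independent draws from a zero-mean Gaussian whose covariance is
a block matrix: 1 on the diagonal, `withinCoupling` inside planted modules,
and a per-state between-module coupling — a scalar, or a module-pair matrix
so that specific pairs can merge in a state. States switch on frame
boundaries. Optional white noise and optional convolution with a canonical
double-gamma kernel sit on top. Non-positive-semidefinite targets are
construction errors naming the state: ground truth is never silently
repaired. Defaults emulate a resting acquisition of 375 regions (twelve
near-equal modules), 216 frames at TR 2.2 s, within 0.5 / between 0.1,
no added noise.

On top of single runs:

* `generateTaskRun()` maps block conditions to between-module couplings
  (an inverted-U load profile is just a non-monotone map);
* `generateCrossoverCohort()` builds pre/post x drug/placebo cohorts with
  Gaussian per-subject intercepts on coupling (default sd 0.02) and a
  post-drug coupling shift;
* `generatePupil()` emits a lagged (optionally smoothed) copy of the
  latent integration series plus noise, z-scored. Smoothing defaults to
  off so the noiseless trace is an exact lagged copy.

What the generator *does not* emulate: temporal autocorrelation of real
BOLD (unless HRF smoothing is enabled), physiological noise, motion
artifacts, spatial autocorrelation within parcels, and inter-regional
variance differences. Passing tests therefore show the pipeline's
correctness and statistical calibration under a modular Gaussian regime,
not robustness to fMRI artifacts.

# What sampling noise does to per-window recovery

A point that shapes how per-window results should be read: with $w = 15$
derivative samples per window, the empirical mean coupling between two
10-region modules fluctuates with a standard deviation near 0.2 around its
target. Even in a strong-contrast regime (within 0.8 / between 0.1) the
merge threshold implied by the configuration null at $\gamma = 1.1$ is
regularly crossed by chance, so a substantial fraction of 15-frame windows
genuinely favour merged partitions, and *every-window* exact recovery of
the planted modules is not attainable — at any resolution, for any
generator with frame-wise sampling noise. This is a property of short
windows, not of the implementation: the time-averaged graph of the same
runs recovers the planted partition perfectly (NMI = 1), and windows of
40+ frames recover it in every window. The acceptance suite states the
strong-contrast windowed criterion at $w = 15$ as given and reports the
measured minimum NMI; the module tests additionally pin the regimes where
exact recovery does hold, so a regression in the detector is still caught.

# Problem sizes used in the validation suite

Simulation studies are run at sizes chosen once for statistical
informativeness: covariance checks at $T = 2000$–5000; recovery and
state-tracking at 40 regions; crossover power at 100 cohorts of 20 subjects
(20 regions, 90 frames, 4 runs each, consensus 3 reps, 20 x 20 bins) per
arm; surrogate-test calibration at 500 repetitions x 200 surrogates
(20 regions, 216 frames, order 6); permutation/Dunn–Clark calibrations at
2000 repetitions; bootstrap coverage at 1000 repetitions; pupil recovery
and null at 12 and 40 cohorts of 8 subjects. Consensus repetitions default
to 500 for real analyses; simulation studies use 3–20 because with strong
planted structure the partitions are already unanimous.

# Known limitations

* The Louvain heuristic is not an exact maximiser; on structureless graphs
  different basins tie closely (tests allow for this explicitly).
* The Dunn–Clark dependency correction with `rCross != 0` is a first-order
  Fisher-z approximation.
* DVARS as percent signal change requires data on an acquired positive
  scale; demeaned data error out.
* The VAR null matches covariance exactly but autocovariance only through
  the fitted coefficients; heavy subspace truncation (regions >>
  `subspaceDim`) whitens fine temporal structure.
* Band-pass edge handling uses odd-reflection padding; the first/last few
  windows of a run inherit filter transients, as in any zero-phase design.
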