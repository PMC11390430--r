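---
title: "Quantifying neural synchrony with dynamic time warping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural synchrony with dynamic time warping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeDTW)
```

## The scientific problem

Multi-electrode recordings of the rodent medial prefrontal cortex (mPFC)
during working-memory tasks such as T-maze alternation yield two kinds of
time series per trial: spike trains (action-potential times per sorted
neuron) and local field potentials (LFPs, the extracellular voltage per
electrode). A central question is whether neurons fire *in concert* —
whether the network's synchronicity structure is stable within a session,
drifts across days, differs between animals, and carries information about
behaviour (did the rat make the correct choice?).

spikeDTW implements a deliberately parameter-free analysis of that
question. Each trial is reduced to a four-second window centred on the
decision moment — 2 s before the rat leaves the T-intersection and 2 s
after — and every pair of simultaneously recorded units is compared by
dynamic time warping (DTW). The pairwise DTW matrix is then summarised by
one scalar per segment, the critical connectivity threshold
$d_\mathrm{crit}$, and a battery of non-parametric tests operates on the
resulting tidy table over the hierarchy *study → rat → session → trial →
timing segment*.

## Dynamic time warping as implemented

For sequences $x_{1..n}$, $y_{1..m}$ the DTW dissimilarity is the minimal
accumulated cost over all monotone, boundary-anchored warping paths with
per-step cost $|x_i - y_j|$ and steps $\{(-1,0), (0,-1), (-1,-1)\}$:

$$D(i,j) = |x_i - y_j| + \min\{D(i-1,j),\; D(i,j-1),\; D(i-1,j-1)\}.$$

Deliberate choices, all in the direction of fewer tunables:

* **No window constraint, no smoothing, no path normalization.** The total
  (unnormalized) cost is returned, so spike-train distances are in
  milliseconds and LFP distances in volts.
* **Spike trains are aligned on their spike-time sequences**, not on
  binned rates. The per-step cost is then a time difference, which is what
  makes a millisecond-valued distance meaningful.
* **Sparse trains are excluded, not imputed.** DTW is undefined on an
  empty sequence; units below `minSpikes` (default 1 spike per 2 s
  segment) are dropped and recorded in the matrix's exclusion log, so
  every exclusion is auditable downstream.
* **LFPs are used at native sampling** (no downsampling or filtering).

DTW is a dissimilarity, not a metric — the triangle inequality is not
asserted anywhere. The implementation (a two-row dynamic program in C++)
is verified in the test suite against exhaustive enumeration of all
warping paths for short sequences.

## The connectivity threshold $d_\mathrm{crit}$

Thresholding a DTW matrix at $t$ gives an undirected, unweighted graph
with an edge wherever $D_{ij} \le t$. That graph is edgeless for small
$t$ and complete for large $t$; $d_\mathrm{crit}$ is the smallest $t$ at
which it is *connected*, located by binary search over the sorted unique
off-diagonal weights with a depth-first-search connectivity check at each
probe. Two conventions are fixed here: the comparison is inclusive
($\le t$), so $d_\mathrm{crit}$ is always an attained edge weight, and
ties collapse because the search runs over unique weights. So defined,
$d_\mathrm{crit}$ equals the bottleneck (maximum edge) of a minimum
spanning tree — the test suite checks that equivalence against an
independent MST implementation on hundreds of random instances.
$\log_{10} d_\mathrm{crit}$ is carried alongside for reporting only; every
statistic operates on the linear scale.

## The statistical battery

All tests are deliberately non-parametric (small samples, unknown
distributions); $\alpha = 0.05$ throughout and no multiple-testing
correction is applied — each screen reports its family size so users can
correct post hoc.

* **Normality screen.** Shapiro-Wilk per session (per modality, optionally
  per correctness/timing stratum) on the session's $d_\mathrm{crit}$
  values; groups under 3 observations or with zero variance are skipped
  and excluded from the reported proportion.
* **Variance screens.** Kruskal-Wallis (and, for comparison, one-way
  ANOVA) at three levels: trial-to-trial within a session, day-to-day
  within a rat, rat-to-rat within a study. Units with a single group are
  excluded with reason `dof = 0` (a rat recorded on one day has no
  day-to-day contrast). Within a session the groups are trials and the
  observations are each trial's two segment values (before and after);
  nothing else yields more than one observation per group. A caveat
  documented by the tests: with only two observations per group the
  Kruskal-Wallis chi-square approximation is strongly *conservative*
  (null rejection well below $\alpha$); calibration checks therefore use
  two balanced groups (the `groups = "timing"` variant), where both tests
  hold their nominal level.
* **Boschloo's exact unconditional test** compares two significance
  proportions. The statistic is the one-sided Fisher exact p-value; the
  reported p-value is its maximal null probability over the nuisance
  success proportion (grid search plus local refinement), which makes the
  test uniformly more powerful than Fisher's conditional test — a
  property the suite asserts table by table. Two-sided p-values are twice
  the smaller one-sided value, capped at 1. Rows of the input are the two
  binomial samples. One reproducibility note: the published reference
  values that `scripts/acceptance.R` recomputes correspond to tables
  whose rows are (significant counts, group totals) — count versus
  *total*, not count versus complement. The script forms the tables that
  way so the reference numbers are reproduced exactly; `boschlooTest`
  itself is a standard correct implementation and accepts any 2×2 table
  of binomial rows.
* **Electrode analyses.** Pooled DTW entries are labelled same- versus
  different-electrode through the grid geometry (spacing 0.25 mm per grid
  unit; same-electrode spike pairs count as distance zero, which cannot
  occur for LFPs since those units *are* electrodes). The two pooled
  groups are compared by Welch's t-test and the two-sample KS test;
  thresholding the distance as a same-electrode classifier yields an ROC
  curve and AUC (via pROC). Distance-stratified medians carry 95%
  percentile-bootstrap intervals (default 1,000 resamples, deterministic
  given a seed).
* **Mantel before/after procedure.** For every ordered pair of trials in
  a session, the Pearson correlation between the before-matrix of trial
  $i$ and the after-matrix of trial $j$ (upper triangles, over the
  session-wide common unit set) is tested by joint row/column permutation
  (two-sided on $|r|$, $p = (1 + \#\{|r_\mathrm{perm}| \ge
  |r_\mathrm{obs}|\})/(n_\mathrm{perm}+1)$, so $p$ is never 0). The
  same-trial ($i = j$) and different-trial pools of $r$ (and of $p$) are
  then compared by Kruskal-Wallis and KS tests: a trial-specific
  correspondence shows up as stochastically larger same-trial
  correlations. Sessions with fewer than 2 usable trials or fewer than 3
  common units are skipped with a reason.

## The synthetic session generator

No public generative model exists for these recordings, so the package
ships one with known ground truth. Neurons are partitioned into
`nClusters` synchrony assemblies (contiguously over electrodes, so
same-electrode pairs tend to share an assembly — giving the electrode
analyses a true signal). Per 2 s segment, each assembly draws a common
parent Poisson process at `baseRate`; each member neuron copies each
parent spike with probability $s$ = `syncCopyProb` (Gaussian jitter,
`jitterSd` = 5 ms, clipped to the segment to preserve counts) and adds an
independent Poisson background at rate $(1-s)\,\cdot$`baseRate`. The
thinning construction keeps every neuron's total rate at `baseRate`
regardless of $s$, so the synchrony knob is orthogonal to the firing
rate; at $s = 0$ spike counts are exactly Poisson (verified by a
goodness-of-fit test), and mean pairwise DTW decreases monotonically in
$s$ (verified over replicate simulations). LFPs are a cluster-shared
8 Hz (theta-band) sinusoid of ~100 µV amplitude plus white noise,
sampled at 1 kHz; electrodes average the phases of the assemblies they
host.

Injected effects: `effectTiming` scales $s$ multiplicatively in the after
segment, `effectCorrect` on correct trials, and `sessionDriftSd`
log-normally perturbs the base rate per session ("resting-state" drift —
a stand-in with no literature-backed magnitude).

**Default study conditions.** 3 rats × 3 sessions × 20 trials; 4
electrodes (2×2 grid) × 4 neurons; 2 assemblies; `baseRate` 5 events/s;
$s = 0.3$; `effectTiming` 1.0 (synchrony doubles after the decision —
a strong but plausible post-decision engagement effect, and the regime in
which a 20-trial session gives the within-session timing screen ~95%
power); `effectCorrect` 0.3; `pCorrect` 0.75. The cluster count matters
more than one might expect: $d_\mathrm{crit}$ is an MST bottleneck, and
with many assemblies the bottleneck edge is usually a *cross*-assembly
distance, which synchrony barely moves — detection power at the same
effect size drops from ~0.95 with 2 assemblies to ~0.23 with 8. Two
assemblies is the cleanest regime for parameter-recovery work and is the
default.

**What the generator does not emulate:** refractory periods, bursting,
non-stationary rates within a segment, spike-sorting errors, 1/f LFP
background, volume conduction, or the exact trial counts of any real
study. Passing tests on synthetic bundles therefore demonstrate the
*statistical machinery* (calibration, power at documented effect sizes,
parameter recovery), not fidelity to any particular biological dataset.

## Experiment-design calculator

If the mPFC hosts $c$ interchangeable synchrony clusters sampled
uniformly at random by an electrode (sampling with replacement, valid
while $c \ll N_\mathrm{mPFC}$), the expected number of neurons needed to
see every cluster is the coupon-collector quantity $S = c\,H_c$, and to
see $k$ of them $S_k = c\,(H_c - H_{c-k})$; both are exposed along with a
Monte-Carlo simulator (used by the tests to verify the closed forms to
within 1%) and the inverse question — the largest $c$ an electrode of
$n$ neurons can expect to cover, found by monotone search. Note the
direction of the monotonicities: $S_k$ grows with $k$ and with $c$ at
full coverage, but for a *fixed* $k$ it decreases toward $k$ as $c$
grows. The volume-scaling estimate
$N_\mathrm{mPFC} = N_\mathrm{brain} \times V_\mathrm{mPFC} /
V_\mathrm{brain}$ with the standard rat values ($2.1\times10^7$ neurons,
2,500 mm³ brain, 20 mm³ mPFC) gives $1.7\times10^5$ mPFC neurons (two
significant figures); the uniform-density assumption is the stated
caveat.

## Numerical and reproducibility choices

* Every stochastic routine takes a seed and restores the caller's RNG
  state; the pipeline derives per-stage seeds from one master seed and
  records them in its manifest, whose per-stage counts must reconcile
  (analyzed + skipped = total).
* The Boschloo nuisance maximization uses a 501-point grid with local
  refinement; the suite pins the results to an independent reference
  implementation at 1e-4.
* Test and calibration problem sizes (e.g. 250 replicates per null
  screen, 100 sessions per recovery arm, sequences ≤ 6 for exhaustive
  DTW enumeration, n ≤ 12 for MST cross-checks) are chosen so the whole
  suite runs in a few minutes while keeping binomial confidence bands
  tight enough to be informative.

## Known limitations

The package analyses synchrony through one lens (unconstrained DTW) and
one summary ($d_\mathrm{crit}$); it does not implement Fourier/wavelet
comparisons, windowed or derivative DTW variants, community detection on
the weighted graph, mixed-effects modelling of the hierarchy, or any
multiple-testing correction. The session-level Kruskal-Wallis screen
inherits the conservativeness of two-observation groups discussed above;
treat its rejection proportions as lower bounds.
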