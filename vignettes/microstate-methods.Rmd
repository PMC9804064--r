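---
title: "Source-space microstate analysis: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space microstate analysis: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the method left them open.

## 1. The segmentation model

A microstate analysis treats parcel-level EEG as a piecewise-constant
sequence of spatial patterns: at each moment one of $k$ unit-norm maps
$a_1, \dots, a_k \in \mathbb{R}^P$ is active, scaled by a fluctuating
amplitude. Segmentation operates on **GFP peaks** — samples where the
spatial standard deviation across parcels is locally maximal and the
topography is most reliable.

**GFP definition.** We use the spatial population standard deviation with
the spatial mean removed (the sensor-space convention retained in source
space); an RMS variant without demeaning is exposed via
`compute_gfp(method = "rms")` for envelope-like inputs whose mean is
meaningful. Peaks are strict local maxima, plateaus counted once at their
leftmost sample, endpoints excluded — no minimum peak distance and no
amplitude floor, so the peak oracle stays trivial and reproducible.

**Polarity invariance.** Parcel time courses obtained as first principal
components of voxel clusters have arbitrary sign, so by default a map and
its negation are the same state: assignment maximizes squared spatial
correlation, and the centroid update is the first principal direction
(rather than the mean) of the member maps. `polarity_invariant = FALSE`
switches both steps to their sign-sensitive analogues.

**"Minimum distance" in backfitting** is implemented as
$1 - \mathrm{corr}^2$, consistent with the GEV objective that the
clustering maximizes; non-peak samples inherit the label of the temporally
nearest peak (ties to the earlier peak, terminal segments to the terminal
peak). No temporal smoothing or minimum-duration post-processing is
applied.

**Model order** is selected on the GEV-vs-$k$ curve with the kneedle rule:
normalize both axes to $[0,1]$, form $d = y_{norm} - x_{norm}$, and take
the $k$ at the global maximum of $d$ among local maxima clearing the
sensitivity threshold $S \cdot \overline{\Delta x}$ (default $S = 1$). An
exactly linear curve has no knee; the fitting wrapper then falls back to
the smallest $k$ whose GEV increment drops below 1% and says so.

Defaults: 20 restarts, tolerance $10^{-6}$ on the GEV change, 500
iterations — ordinary choices for a k-means of this size; empty clusters
are reseeded at the worst-fit sample. Clustering is pooled across all
scans (one shared map set); per-group clustering is possible by calling
the fitter on each group's peak pool.

## 2. Sequence statistics

For a labeled sequence at sampling rate $f_s$: per-class mean duration
(mean run length $\times 1000/f_s$ ms), coverage (fraction of samples) and
occurrence (runs per second). Scan-edge-truncated runs are *included* in
the duration means by default, which keeps the identity
$\mathrm{occurrence} \times \mathrm{duration}/1000 = \mathrm{coverage}$
exact; `exclude_boundary_runs = TRUE` drops them.

**Syntax** is defined on run transitions (the diagonal is structurally
zero): sample-wise counting would mix dwell time into the transition
structure. Group-level syntax is the unweighted mean of per-scan
probability matrices so long scans do not dominate. The surrogate test for
non-random syntax preserves the run-label multiset and forbids adjacent
repeats; surrogates are drawn by count-weighted sequential construction
with restart on dead ends. (Uniform rejection sampling of full
permutations, the textbook construction, has acceptance probability
$\approx (1-1/k)^{n_{runs}}$ — about $10^{-18}$ for a hundred runs of
three states — so it is unusable beyond toy sequences; the sequential
construction is the standard practical surrogate and is near-uniform for
balanced multisets.) P-values use the $+1$ correction,
$p = (1 + \#\{\text{surrogate} \ge \text{observed}\})/(1 + n)$, so they
are never zero.

### The Hurst exponent and its crossover

The memory of a symbolic sequence is estimated by embedding it as random
walks: for each bipartition of the label set, samples map to $\pm 1$
increments, and detrended fluctuation analysis (DFA) of the integrated
walk gives a scaling exponent; the estimate is the mean over all
$2^{k-1}-1$ bipartitions ($k \le 8$; a seeded sample of 63 otherwise).

A point that matters in practice: below roughly 50 mean dwell times the
walk is in the **ballistic crossover** imposed by the runs themselves —
within a run all increments are equal, so the local DFA slope approaches
1.4 at window sizes comparable to the dwell and only decays to the true
asymptotic exponent far above it. Fitting windows of 10–1000 samples on a
sequence with 100-ms dwells at 250 Hz therefore measures dwell length, not
memory (slopes near 1 even for memoryless sequences). The default window
range is consequently *adaptive*: from $\max(10, 50 \times
\overline{\text{run length}})$ samples up to a tenth of the sequence, with
10 log-spaced sizes. An explicit `scale_range` is honored. With this
range, memoryless semi-Markov sequences read $H \approx 0.5$ and the
estimator's null behavior matches the iid case.

## 3. The synthetic cohort: what it emulates

The generator produces the structure the analysis assumes, with ground
truth attached, standing in for restricted patient data:

- **Maps:** $k$ spatially demeaned unit-norm Gaussian maps, rejection
  sampled until all pairwise $|corr| \le$ a cap (default 0.5), keeping
  states identifiable. A zero cap constructs an orthonormal set directly.
- **Sequences:** semi-Markov — runs follow a zero-diagonal transition
  matrix, dwell times are gamma with per-state mean (default 100 ms, the
  canonical microstate timescale) and shape (default 2: peaked,
  quasi-stable; shape 1 recovers the memoryless regime), truncated at one
  sample.
- **Signal:** the active map scaled by a rectified 1–30 Hz noise envelope
  (unit per-parcel RMS, so GFP peaks arise naturally), plus white noise of
  standard deviation `noise_sd` — an amplitude SNR of
  $1/\texttt{noise\_sd}$ — band-limited to 1–30 Hz. The default
  `noise_sd = 0.5` (SNR 2) leaves peak-map clustering comfortably solvable
  without being trivial.
- **Coupling:** per-state narrowband phase-lagged pairs. A shared analytic
  carrier is injected into both parcels with a fixed phase offset, at
  twice the map-component RMS at full strength so that planted synchrony
  dominates the broadband background within its band.
- **Groups:** multiplicative offsets on dwell means and additive offsets
  on transition logits, matching the direction of the clinical effects the
  pipeline is meant to detect (shorter durations, shifted syntax).

### Long-range dependence needs state-selective modulation

The obvious way to plant a target Hurst exponent — modulating all dwell
times by one fractional-Gaussian-noise (fGn) series — provably does
nothing to the label sequence as seen by the DFA estimator: inside a
fixed-length window the walk sum is $\sum_r (s_r - \mu)\, d_r$ with run
signs $s_r$ independent of durations $d_r$, so duration fluctuations
cancel and $H \to 0.5$ regardless of the modulation (we verified this
empirically before discarding the design). The label sequence only
inherits long memory if *occupancy* fluctuates slowly. The generator
therefore gives each state its own independent fGn **excitability field**
with the target Hurst index: the current state's field value is
rank-mapped through its gamma quantile function (preserving the gamma
dwell marginal — excitable states dwell longer) and simultaneously biases
the next-state logits with coupling `lrd_coupling` (default 1.5 —
excitable states are also entered more often). Durations still carry the
long memory, but state-selectively, so coverage tracks the fields and
every bipartition walk sees it.

Calibration at these defaults (600-s scans): `target_hurst = 0.8` yields
DFA estimates of ≈ 0.70 ± 0.03 — the estimator is conservative at finite
scan lengths because the accessible window range sits just above the dwell
crossover — and unmodulated sequences yield 0.50 ± 0.02. The knob is
therefore ordinal rather than exactly calibrated; tests assert the
recovery band (0.65, 0.95) for a 0.8 target and $H > 0.5$ persistence.

### What passing tests do and do not show

The generator emulates piecewise-constant topographies, gamma dwell
structure, planted syntax, long-memory occupancy, narrowband phase
coupling and additive white noise. It does **not** emulate anatomically
realistic map geometry, 1/f background spectra, volume-conduction mixing,
artifacts, or inter-subject map variability. Passing recovery tests shows
the estimators are correct and calibrated under the stated generative
model — not that real patient EEG satisfies that model.

## 4. Connectivity and MVPA

Per band (δ 1–4, θ 4–8, α 8–13, β 13–30 Hz) the analytic signal comes from
a zero-phase Butterworth bandpass followed by the Hilbert construction;
both are spectral multiplications and share one FFT pass (the
forward–backward squared-magnitude response of the 4th-order filter is
applied in the frequency domain — phase-free by construction, with
circular boundary handling appropriate for long resting-state records).

Samples of one state are concatenated in time order — as in the original
design, accepting phase discontinuities at the seams — and chopped into
non-overlapping 5-s windows; tails are dropped. wPLI is the original
(non-debiased) estimator, computed per window and aggregated per state as
the ratio of summed numerator and denominator components, which makes the
static (all-window) matrix exactly the window-count-weighted aggregation
of the per-state pieces. Pairs whose $|\mathrm{Im}|$ mass is at round-off
level relative to their amplitude product (exactly zero-lag coupling, zero
signal) are defined to have wPLI 0.

A subtlety found while calibrating the decoder: even with no planted
coupling, scans whose states have *distinct* spatial maps decode slightly
above chance (~2 accuracy points in our validation setting), because the
per-pair wPLI noise floor depends on each parcel's signal-to-noise, which
follows the active map. That is a small real state signal, not a false
positive; the chance-level calibration of the MVPA machinery is therefore
established on a null in which all states share one map and window
features are exchangeable by construction.

One consequence of ratio aggregation worth knowing when reading
deviation-from-static edge lists: a strong coupling confined to one state
contributes most of the $\mathrm{Im}$ mass, so the *static* value of that
edge is pulled toward the coupled state's value and the deviation shows up
mainly as a strong negative value in the *other* states. The planted edge
still dominates the ranking; its sign pattern is the signature.

The MVPA classifier is a ridge-regularized linear discriminant (pooled
within-class covariance plus $\lambda \cdot \overline{\mathrm{diag}}$,
default $\lambda = 0.1$, with an absolute floor so noise-free features
remain solvable), chosen for determinism and speed; features are
standardized with training-fold statistics inside a stratified 5-fold
cross-validation. No installed package provides a regularized LDA, and an
unregularized one fails on the near-collinear degree features, hence the
small in-package implementation. The permutation null re-runs the full
cross-validation on uniformly permuted labels;
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1+n_{perm})$. Windows are
pooled across scans; scan identity travels with the features so grouped
cross-validation can be layered on if desired.

## 5. Group analysis

Wilcoxon rank-sum per class and indicator (exact when both groups are ≤ 10
and tie-free, else normal approximation with tie correction and continuity
correction), Benjamini–Hochberg within each indicator's family of $k$
class-wise tests; syntax cells form their own $k(k-1)$-cell family. Both
raw and adjusted p-values are always reported, with explicit columns,
since exploratory syntax contrasts are conventionally read at both levels.
Shapiro–Wilk annotates distributions but never gates the nonparametric
tests. Demographic tables use chi-square (Fisher when any expected cell
< 5) for categorical rows and Welch's t (or Wilcoxon, by option) for
continuous rows, formatted clinical-style.

## 6. Numerical choices and degenerate inputs

- Spatially constant maps cannot be normalized; the fitter rejects them.
  Zero total GFP makes GEV undefined (error). Constant label sequences
  have no Hurst exponent (error). Sequences with fewer than two runs have
  no syntax (error).
- Scans with fewer detected peaks than requested contribute all their
  peaks with a warning, keeping cohort totals well-defined.
- Transition matrices with an all-zero row (absorbing states) are invalid
  generator input; empty *observed* rows in fitted syntax matrices stay
  zero and are flagged.
- Ties: assignment ties take the first centroid; equidistant peaks take
  the earlier; edge-deviation ties order by (state, i, j).
- All stochastic steps take a seed; per-scan and per-stage seeds are
  derived from a master seed through one documented splitting rule
  (a seeded draw of sub-seeds), so any stage can be reproduced alone.

## 7. Problem sizes used in validation

The validation suite exercises the full pipeline at a reduced but
study-shaped scale chosen to run comfortably on a single CPU: the
recovery cohort uses the study's 84 scans × 600 s with 78 parcels and
seven planted states (pairwise map correlation ≤ 0.5, SNR 2) sampled at
100 Hz with 500 peaks per scan and 3 clustering restarts; chance-level
MVPA calibration uses 10-parcel, 250-s scans (20 repeats for accuracy, 200
for permutation-p uniformity at 100 permutations); Hurst calibration uses
20 sequences of 600 s at 250 Hz. The acceptance script reports the minimum
Hurst exponent across 20 long-range-dependent synthetic subjects at the
full 250 Hz / 600 s sequence scale.

## 8. Known limitations

- Winner-take-all labeling: no soft assignment, no minimum-duration
  smoothing; fragmented backfit sequences shorten apparent durations
  relative to generative dwell times when noise is high.
- The frequency-domain zero-phase filter has circular boundary handling;
  for scans shorter than a few filter time constants, edge samples are
  contaminated (irrelevant at the 600-s design scale).
- The kneedle rule assumes a concave-increasing GEV curve; heavily
  under-restarted fits can produce non-monotone curves (a warning is
  raised) and unstable knees.
- The Hurst estimator needs sequences much longer than 50 dwell times;
  at 600 s and 100-ms dwells the usable scaling range is barely over one
  decade, and estimates of strongly persistent sequences are biased
  downward (documented above).
- Group syntax averaging assumes every scan visits every state; rows
  empty in any scan are flagged rather than re-weighted.
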