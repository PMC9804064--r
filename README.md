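# microdyn

Source-space EEG **microstate dynamics** for R: segmentation of parcel-level
(region-of-interest) EEG time series into quasi-stable spatial states,
statistics of the resulting state sequences, state-segmented phase-coupling
networks, and two-group nonparametric comparison — together with a fully
seeded synthetic-cohort generator so that every stage of the pipeline can be
validated against known ground truth.

## The problem

Resting-state EEG passes through a small repertoire of quasi-stable spatial
activity patterns ("microstates") lasting tens of milliseconds. In disorders
of consciousness, the temporal structure of these states — how long each
lasts, how often it occurs, which state follows which — differs between
patients in a minimally conscious state (MCS) and a vegetative state (VS),
making microstate statistics candidate markers of consciousness level.
Working in source space (parcel time courses rather than electrodes) ties
the states to anatomy but raises methodological questions — model-order
selection, polarity handling, sequence memory — that this package
implements as a tested, reusable pipeline.

## The method

Given parcel time courses `X ∈ R^{P×T}` band-limited to 1–30 Hz:

1. **GFP peaks.** The global field power `GFP(t) = sd_spatial(X[, t])`
   peaks at moments of high topographic signal-to-noise; a random subsample
   of peak maps per scan (5000 in the original design) is pooled across
   scans for clustering.
2. **Modified k-means.** Peak maps are spatially demeaned and
   L2-normalized; assignment maximizes the squared spatial correlation with
   the centroids (a map and its negation are the same state), and each
   centroid update is the first principal direction of its member maps.
   Fit quality is the **global explained variance**

   `GEV = Σ_t (GFP_t · corr(x_t, a_{L_t}))² / Σ_t GFP_t²`

   with `a_{L_t}` the centroid assigned to sample `t`.
3. **Model order by kneedle.** GEV is computed for `k = 2..20` and the knee
   of the normalized GEV-vs-k curve selects `k`.
4. **Backfitting.** Every GFP peak of a scan takes the label of its closest
   centroid (distance `1 − corr²`); every other sample inherits the label of
   its nearest peak in time.
5. **Sequence statistics.** Per class: mean duration (ms), coverage,
   occurrence (s⁻¹); globally: mean duration, the **syntax matrix** of
   run-to-run transition probabilities (zero diagonal), a surrogate test for
   non-random syntax, and the **Hurst exponent** by bipartition random-walk
   detrended fluctuation analysis (H = 0.5 memoryless, H > 0.5 persistent).
6. **State-specific connectivity.** Per frequency band (δ 1–4, θ 4–8,
   α 8–13, β 13–30 Hz) the analytic signal is segmented by state into 5-s
   windows; the **weighted phase lag index**
   `wPLI_ij = |E Im S_ij| / E |Im S_ij|` (cross-spectrum `S_ij = z_i z_j*`)
   gives per-state networks, and a cross-validated linear classifier
   (MVPA) with a label-permutation null tests whether weighted-degree
   features decode state identity above the `1/k` chance level.
7. **Group comparison.** Wilcoxon rank-sum per class and indicator with
   Benjamini–Hochberg FDR within each indicator family; syntax cells form
   their own family; plus clinical-style cohort summary tables.

Because the patient EEG the method was developed on is not publicly
available, the package ships a **synthetic-cohort generator**: planted
unit-norm state maps with a cap on pairwise correlation, semi-Markov label
sequences (gamma dwell times, zero-diagonal syntax), optional
long-range-dependent dwell/occupancy modulation with a target Hurst
exponent, state-conditional narrowband phase-lagged coupling, and two groups
with planted multiplicative dwell or additive syntax-logit differences.

## Worked example

```r
library(microdyn)

tm <- matrix(1/6, 7, 7); diag(tm) <- 0
maps   <- make_state_maps(k = 7, n_parcels = 78, max_abs_corr = 0.5, seed = 1)
params <- sequence_params(tm, dwell_mean = 100, duration_s = 120, fs = 100)
spec   <- cohort_spec(n_scans = c(MCS = 5, VS = 5), maps = maps,
                      params = params, dwell_multiplier = c(0.8, 1),
                      noise_sd = 0.5, seed = 2)
cohort <- generate_cohort(spec)

pm     <- lapply(cohort$scans, function(ts)
            peak_maps(bandpass(ts), n_peaks = 400, seed = 3))
model  <- microstates(do.call(rbind, lapply(pm, `[[`, "maps")),
                      k = NULL, k_range = 2:12,
                      gfp = unlist(lapply(pm, `[[`, "gfp")),
                      restarts = 5, seed = 4)
model
#> Microstate model: k = 7 states over 78 parcels
#>   GEV = 0.8110 (polarity-invariant, 4000 peak maps, 5 restarts)
#>   model order selected by kneedle over k = 2 .. 12
```

The knee of the GEV curve recovers the seven planted states, which explain
81% of the GFP-weighted spatial variance at the peaks. Backfit one scan and
inspect its sequence statistics:

```r
seqs <- lapply(cohort$scans, function(ts) predict(model, ts))
class_stats(seqs[[1]])
#> Sequence statistics: 1511 runs, global mean duration 79.4 ms
#>  class duration_ms coverage occurrence present
#>      1        81.6   0.1421      1.742    TRUE
#>      2        79.2   0.1683      2.125    TRUE
#>      ...
```

Durations sit near the planted 80 ms (this scan is from the MCS group,
whose dwell times were planted at 0.8 × 100 ms); coverage is near the
uniform 1/7. Compare the groups:

```r
tab <- cohort_stats_table(seqs, cohort$manifest$group, cohort$manifest$scan_id)
cmp <- compare_cohorts(tab)
cmp[cmp$indicator == "duration_ms",
    c("class", "median_MCS", "median_VS", "p_raw", "p_fdr")]
#>   class median_MCS median_VS   p_raw  p_fdr
#> 1     1       81.1      84.0 0.22222 0.2222
#> 2     2       77.7      86.8 0.00794 0.0139
#> 3     3       79.7      88.3 0.00794 0.0139
#> 4     4       78.7      84.9 0.00794 0.0139
#> ...
```

The planted 20% dwell shortening in the MCS group is detected in most
classes after FDR correction — the same analysis logic (and effect
direction) used for the clinical contrast the pipeline was built around.
`run_pipeline(run_config(spec, ...), out_dir)` executes the whole chain —
simulate → filter → peaks → cluster → backfit → statistics → connectivity
MVPA → comparison — writing CSV/JSON artifacts, a JSON-lines log and a
Markdown report, deterministically for a given config.

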