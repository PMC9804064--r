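Package: microdyn
Title: Source-Space EEG Microstate Dynamics and State-Segmented Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Microstate analysis of parcel-level (source-space) EEG time
    series: global field power (GFP) peak extraction, polarity-invariant
    modified k-means clustering of peak maps, model-order selection on the
    global explained variance (GEV) curve by knee-point detection,
    backfitting of microstate labels to full recordings, and sequence
    statistics (per-class duration, coverage, occurrence, transition syntax,
    Hurst exponent by bipartition random-walk detrended fluctuation
    analysis).  Includes microstate-segmented weighted phase lag index
    (wPLI) connectivity with multivariate pattern analysis (MVPA) decoding
    and permutation testing, two-group nonparametric comparison with false
    discovery rate control, and a seeded semi-Markov synthetic-cohort
    generator with planted spatial maps, dwell-time structure, long-range
    dependence and state-conditional phase-lagged coupling for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
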