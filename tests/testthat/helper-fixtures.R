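# shared fixture builders (everything generated in code at test time)

uniform_tm <- function(k) {
  tm <- matrix(1 / (k - 1), k, k)
  diag(tm) <- 0
  tm
}

# hand-built state sequence (bypasses the sampler) for targeted cases
manual_sequence <- function(labels, fs = 250, k = max(labels)) {
  structure(list(labels = as.integer(labels), fs = fs, k = k,
                 peak_indices = NULL, source = "ground_truth"),
            class = "state_sequence")
}

# Demographics table assembled from published cohort counts (synthetic rows;
# only the marginal counts matter for the percentage arithmetic)
doc_demographics <- function() {
  sex <- c(rep("Female", 16), rep("Male", 11),    # MCS: 27
           rep("Female", 34), rep("Male", 23))    # VS: 57
  etiology <- c(rep("Anoxia", 8), rep("Stroke", 12), rep("TBI", 7),
                rep("Anoxia", 18), rep("Stroke", 27), rep("TBI", 12))
  set.seed(6)
  data.frame(scan_id = sprintf("p%03d", 1:84),
             group = rep(c("MCS", "VS"), c(27, 57)),
             sex = sex, etiology = etiology,
             age = round(c(rnorm(27, 44, 14.2), rnorm(57, 45.6, 14.9))),
             post_injury_months = round(c(rexp(27, 1 / 15.9),
                                          rexp(57, 1 / 6)), 1))
}

# small rendered scan with known structure, cached per options
small_scan <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1, k = 4, p = 12, duration_s = 30, fs = 100,
           noise_sd = 0.3, coupling = NULL) {
    key <- paste(seed, k, p, duration_s, fs, noise_sd,
                 is.null(coupling), collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    maps <- make_state_maps(k, p, seed = seed)
    sq <- sample_state_sequence(
      sequence_params(uniform_tm(k), dwell_mean = 100,
                      duration_s = duration_s, fs = fs), seed = seed + 1)
    ts <- render_timeseries(sq, maps, coupling = coupling,
                            noise_sd = noise_sd, seed = seed + 2)
    out <- list(maps = maps, seq = sq, ts = ts)
    cache[[key]] <- out
    out
  }
})
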