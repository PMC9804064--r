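#' Generate a set of identifiable microstate maps over parcels
#'
#' Draws `k` spatial maps over `n_parcels` regions by rejection sampling of
#' spatially demeaned Gaussian vectors until every pair of distinct maps has
#' absolute spatial correlation at most `max_abs_corr`.  Each map has unit L2
#' norm.  When `max_abs_corr = 0` and `k <= n_parcels` an orthonormal basis is
#' constructed directly (QR of a random Gaussian matrix).
#'
#' @param k number of states (>= 2).
#' @param n_parcels number of parcels (>= k).
#' @param max_abs_corr cap on pairwise absolute spatial correlation between
#'   distinct maps; keeps the states identifiable for clustering.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param parcel_labels optional character vector of parcel names.
#' @param max_tries rejection-sampling budget before giving up.
#' @return an object of class `"state_maps"`: list with `maps` (k x n_parcels,
#'   unit-norm rows), `k`, and `parcel_labels`.
#' @export
make_state_maps <- function(k, n_parcels, max_abs_corr = 0.5, seed = NULL,
                            parcel_labels = NULL, max_tries = 1000L) {
  stopifnot(k >= 2, max_abs_corr >= 0, max_abs_corr <= 1)
  if (k > n_parcels)
    stop("k (", k, ") cannot exceed n_parcels (", n_parcels, ")")
  if (is.null(parcel_labels))
    parcel_labels <- sprintf("P%03d", seq_len(n_parcels))
  stopifnot(length(parcel_labels) == n_parcels)

  maps <- with_seed(seed, {
    if (max_abs_corr == 0) {
      # exact construction: orthonormal columns of a random Gaussian QR
      q <- qr.Q(qr(matrix(stats::rnorm(n_parcels * k), n_parcels, k)))
      t(q)
    } else {
      found <- NULL
      for (i in seq_len(max_tries)) {
        m <- matrix(stats::rnorm(k * n_parcels), k, n_parcels)
        m <- normalize_rows(m, demean = TRUE)
        cc <- m %*% t(m)
        if (max(abs(cc[upper.tri(cc)])) <= max_abs_corr) {
          found <- m
          break
        }
      }
      if (is.null(found))
        stop("could not satisfy max_abs_corr = ", max_abs_corr,
             " within ", max_tries, " tries")
      found
    }
  })
  dimnames(maps) <- list(sprintf("state%d", seq_len(k)), parcel_labels)
  structure(list(maps = maps, k = k, parcel_labels = parcel_labels),
            class = "state_maps")
}

#' Sequence-generation parameters for the semi-Markov state simulator
#'
#' @param transition_matrix k x k row-stochastic matrix with zero diagonal
#'   giving the between-run transition probabilities (microstate syntax).
#' @param dwell_mean per-state mean dwell time in milliseconds (recycled to
#'   length k).
#' @param dwell_dispersion gamma shape parameter of the dwell distribution;
#'   1 gives an exponential (Markov) regime, larger values a peaked
#'   quasi-stable regime.
#' @param target_hurst optional Hurst index in (0.5, 1); when set, every state
#'   gets an independent fractional Gaussian noise "excitability" field with
#'   this Hurst index: a state's field value is rank-mapped through its gamma
#'   quantile function to give the dwell draw (preserving the gamma marginal)
#'   and simultaneously biases the transition logits toward currently
#'   excitable states, so occupancy -- and hence the label sequence --
#'   inherits the long-range dependence.  Purely symmetric dwell modulation
#'   (identical across states) provably cancels inside fixed-length analysis
#'   windows and leaves the label sequence memoryless, which is why the
#'   modulation is state-specific.
#' @param lrd_coupling strength of the excitability bias on the transition
#'   logits (only used with `target_hurst`).
#' @param duration_s scan length in seconds.
#' @param fs sampling rate in Hz.
#' @return an object of class `"sequence_params"`.
#' @export
sequence_params <- function(transition_matrix, dwell_mean = 100,
                            dwell_dispersion = 2, target_hurst = NULL,
                            lrd_coupling = 1.5, duration_s = 600, fs = 250) {
  tm <- as.matrix(transition_matrix)
  k <- nrow(tm)
  stopifnot(ncol(tm) == k, k >= 2, all(tm >= 0), fs > 0, duration_s > 0)
  if (any(diag(tm) != 0))
    stop("transition_matrix must have an exactly zero diagonal")
  rs <- rowSums(tm)
  if (any(rs == 0))
    stop("transition_matrix has an all-zero row (absorbing/unreachable state)")
  if (any(abs(rs - 1) > 1e-9))
    stop("transition_matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  dwell_mean <- rep_len(dwell_mean, k)
  dwell_dispersion <- rep_len(dwell_dispersion, k)
  stopifnot(all(dwell_mean > 0), all(dwell_dispersion > 0))
  if (!is.null(target_hurst))
    stopifnot(target_hurst > 0.5, target_hurst < 1)
  structure(list(transition_matrix = tm, k = k, dwell_mean = dwell_mean,
                 dwell_dispersion = dwell_dispersion,
                 target_hurst = target_hurst, lrd_coupling = lrd_coupling,
                 duration_s = duration_s, fs = fs),
            class = "sequence_params")
}

# stationary distribution of an ergodic row-stochastic matrix
stationary_dist <- function(tm) {
  e <- eigen(t(tm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Runs alternate between states according to `transition_matrix` (zero
#' diagonal, so successive runs never share a label); each run's dwell time is
#' drawn from a gamma distribution with the state's mean and shape, truncated
#' at one sample.  With `target_hurst` set, each state carries an independent
#' fractional Gaussian noise excitability field: the current state's field is
#' mapped through its gamma quantile function to give the dwell draw, and the
#' fields bias the next-state logits (weight `lrd_coupling`), so both dwell
#' times and occupancy fluctuate with long memory (see [sequence_params()]).
#'
#' @param params a [sequence_params()] object.
#' @param seed integer seed, or `NULL`.
#' @return an object of class `"state_sequence"`: integer `labels` in 1..k
#'   (one per sample), `fs`, `k`, and `source = "ground_truth"`.
#' @export
sample_state_sequence <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sequence_params"))
  n_samples <- round(params$duration_s * params$fs)
  k <- params$k
  mean_samp <- params$dwell_mean * params$fs / 1000
  shape <- params$dwell_dispersion

  with_seed(seed, {
    # buffer size: expected runs under the shortest dwell, plus margin
    cap <- 2L * (ceiling(n_samples / min(mean_samp)) + 50L)
    pi0 <- stationary_dist(params$transition_matrix)
    states <- integer(cap)
    dwells <- integer(cap)
    total <- 0L
    cur <- sample.int(k, 1L, prob = pi0)
    lrd <- !is.null(params$target_hurst)
    # per-state excitability fields, pre-drawn for the worst case
    G <- if (lrd) vapply(seq_len(k), function(s) fgn(cap, params$target_hurst),
                         numeric(cap))
    run <- 0L
    while (total < n_samples) {
      run <- run + 1L
      if (run > cap) {  # extend buffers in the (rare) heavy-truncation case
        old_cap <- cap
        cap <- 2L * cap
        length(states) <- cap
        length(dwells) <- cap
        if (lrd) G <- rbind(G, vapply(seq_len(k), function(s)
          fgn(cap - old_cap, params$target_hurst), numeric(cap - old_cap)))
      }
      u <- if (lrd) stats::pnorm(G[run, cur]) else stats::runif(1)
      d <- stats::qgamma(u, shape = shape[cur],
                         scale = mean_samp[cur] / shape[cur])
      d <- max(1L, as.integer(round(d)))
      states[run] <- cur
      dwells[run] <- d
      total <- total + d
      pr <- params$transition_matrix[cur, ]
      if (lrd) {
        pr <- pr * exp(params$lrd_coupling * G[run, ])
        pr[cur] <- 0
      }
      cur <- sample.int(k, 1L, prob = pr)
    }
    labels <- rep.int(states[seq_len(run)], dwells[seq_len(run)])[seq_len(n_samples)]
    structure(list(labels = labels, fs = params$fs, k = k,
                   peak_indices = NULL, source = "ground_truth"),
              class = "state_sequence")
  })
}

#' Per-state coupling specification for the renderer
#'
#' A data frame describing narrowband phase-lagged parcel-pair coupling that is
#' switched on only while a given state is active.
#'
#' @param state state label (1-based) during which the coupling is active.
#' @param i,j distinct parcel indices.
#' @param band band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`) or a
#'   length-2 numeric `c(lo, hi)` in Hz.
#' @param phase_lag_rad phase lag in (-pi, pi].
#' @param strength coupling strength in `[0, 1]`.
#' @return a data frame of class `"coupling_spec"` (rows rbind-able).
#' @export
coupling_spec <- function(state, i, j, band = "alpha", phase_lag_rad = pi / 2,
                          strength = 1) {
  if (is.character(band)) {
    bd <- eeg_bands()[[match.arg(band, names(eeg_bands()))]]
  } else bd <- band
  stopifnot(length(bd) == 2, bd[1] < bd[2], i != j,
            phase_lag_rad > -pi, phase_lag_rad <= pi,
            strength >= 0, strength <= 1)
  structure(data.frame(state = state, i = i, j = j,
                       lo = bd[1], hi = bd[2],
                       phase_lag_rad = phase_lag_rad, strength = strength),
            class = c("coupling_spec", "data.frame"))
}

#' Render a parcel time-series matrix from a label sequence and state maps
#'
#' The signal at sample t with active state s is a broadband (1-30 Hz)
#' rectified-noise amplitude envelope times the state's spatial map (scaled so
#' the map component has unit per-parcel RMS), plus any state-conditional
#' narrowband phase-lagged coupling pairs, plus white noise; the sum is
#' band-limited to 1-30 Hz.  GFP peaks arise naturally from the envelope.  At
#' full strength a coupling component is injected at twice the map-component
#' per-parcel RMS so that planted synchrony dominates the broadband background
#' within its band.
#'
#' @param seq a `"state_sequence"`.
#' @param maps a `"state_maps"` object with `maps$k >= max(seq$labels)`.
#' @param coupling optional `coupling_spec` data frame (rows rbind-ed).
#' @param noise_sd white-noise SD relative to the unit-RMS map component.
#' @param seed integer seed, or `NULL`.
#' @param scan_id,group metadata carried on the returned object.
#' @return an object of class `"parcel_ts"`: `data` (n_parcels x n_samples),
#'   `fs`, `parcel_labels`, `scan_id`, `group`.
#' @export
render_timeseries <- function(seq, maps, coupling = NULL, noise_sd = 0.5,
                              seed = NULL, scan_id = "scan", group = NA) {
  stopifnot(inherits(seq, "state_sequence"), inherits(maps, "state_maps"))
  if (max(seq$labels) > maps$k)
    stop("sequence uses label ", max(seq$labels), " but maps has k = ", maps$k)
  stopifnot(noise_sd >= 0)
  p <- ncol(maps$maps)
  n <- length(seq$labels)
  fs <- seq$fs

  with_seed(seed, {
    env <- abs(bandpass_vector(stats::rnorm(n), 1, 30, fs))
    env <- env / sqrt(mean(env^2))
    # outer-product construction: columns are env[t] * sqrt(p) * map[label_t, ]
    x <- t(maps$maps[seq$labels, , drop = FALSE]) *
      rep(env * sqrt(p), each = p)
    if (!is.null(coupling) && nrow(coupling) > 0) {
      for (r in seq_len(nrow(coupling))) {
        cs <- coupling[r, ]
        carrier <- bandpass_vector(stats::rnorm(n), cs$lo, cs$hi, fs)
        z <- analytic_vector(carrier)
        z <- z / sqrt(mean(Re(z)^2))
        gain <- 2 * cs$strength
        mask <- seq$labels == cs$state
        x[cs$i, mask] <- x[cs$i, mask] + gain * Re(z[mask])
        x[cs$j, mask] <- x[cs$j, mask] +
          gain * Re(z[mask] * exp(-1i * cs$phase_lag_rad))
      }
    }
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(p * n, sd = noise_sd), p, n)
    x <- bandpass_mat(x, 1, 30, fs)
    parcel_ts(x, fs = fs, parcel_labels = maps$parcel_labels,
              scan_id = scan_id, group = group)
  })
}

#' Cohort specification for the two-group synthetic generator
#'
#' @param n_scans named integer vector of scans per group, e.g.
#'   `c(MCS = 27, VS = 57)`.
#' @param maps shared `"state_maps"` object.
#' @param params baseline [sequence_params()] shared by both groups.
#' @param dwell_multiplier per-group multiplicative offset on `dwell_mean`
#'   (recycled to the number of groups).
#' @param logit_shift optional per-group list of k x k matrices added to the
#'   log transition probabilities (rows renormalized, diagonal kept zero).
#' @param coupling optional per-group list of `coupling_spec` data frames (a
#'   single data frame is shared by both groups).
#' @param noise_sd additive white-noise SD passed to [render_timeseries()].
#' @param seed master seed; per-scan seeds are derived from it.
#' @param render if `FALSE`, only label sequences (no time series) are
#'   generated -- useful for sequence-level studies.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_scans = c(MCS = 27, VS = 57), maps, params,
                        dwell_multiplier = 1, logit_shift = NULL,
                        coupling = NULL, noise_sd = 0.5, seed = 1L,
                        render = TRUE) {
  stopifnot(all(n_scans >= 1), inherits(params, "sequence_params"))
  if (is.null(names(n_scans)))
    names(n_scans) <- paste0("G", seq_along(n_scans))
  dwell_multiplier <- rep_len(dwell_multiplier, length(n_scans))
  structure(list(n_scans = n_scans, maps = maps, params = params,
                 dwell_multiplier = dwell_multiplier,
                 logit_shift = logit_shift, coupling = coupling,
                 noise_sd = noise_sd, seed = seed, render = render),
            class = "cohort_spec")
}

shift_logits <- function(tm, shift) {
  lt <- log(tm)
  lt[tm == 0] <- -Inf
  lt <- lt + shift
  out <- exp(lt)
  diag(out) <- 0
  out / rowSums(out)
}

#' Generate a labeled two-group synthetic cohort with ground truth
#'
#' Applies each group's dwell-time multiplier and transition-logit shift to the
#' baseline sequence parameters, simulates one semi-Markov label sequence per
#' scan, and (unless `render = FALSE`) renders parcel time series.  Per-scan
#' seeds are derived deterministically from the master seed.
#'
#' @param spec a [cohort_spec()] object.
#' @param out_dir optional directory; when given, each scan is written with
#'   [write_scan()] and a JSON manifest plus ground-truth bundle are written
#'   alongside.
#' @return an object of class `"cohort"`: `scans` (list of `"parcel_ts"`, or
#'   `NULL` when not rendered), `sequences` (ground-truth label sequences),
#'   `manifest` (data frame: scan_id, group, seed), `maps`, `group_params`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n_scans)
  n_total <- sum(spec$n_scans)
  seeds <- derive_seeds(spec$seed, 2L * n_total)
  group_params <- list()
  for (gi in seq_along(groups)) {
    pg <- spec$params
    pg$dwell_mean <- pg$dwell_mean * spec$dwell_multiplier[gi]
    if (!is.null(spec$logit_shift))
      pg$transition_matrix <- shift_logits(pg$transition_matrix,
                                           spec$logit_shift[[gi]])
    group_params[[groups[gi]]] <- pg
  }
  scan_group <- rep(groups, spec$n_scans)
  scan_id <- sprintf("scan%03d", seq_len(n_total))
  sequences <- vector("list", n_total)
  scans <- if (spec$render) vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- scan_group[i]
    sequences[[i]] <- sample_state_sequence(group_params[[g]],
                                            seed = seeds[[2L * i - 1L]])
    if (spec$render) {
      cp <- spec$coupling
      if (!is.null(cp) && !is.data.frame(cp)) cp <- cp[[g]]
      scans[[i]] <- render_timeseries(sequences[[i]], spec$maps, coupling = cp,
                                      noise_sd = spec$noise_sd,
                                      seed = seeds[[2L * i]],
                                      scan_id = scan_id[i], group = g)
    }
  }
  manifest <- data.frame(scan_id = scan_id, group = scan_group,
                         seed = vapply(seeds[seq(1L, 2L * n_total, by = 2L)],
                                       function(s) as.numeric(s %||% NA), 0))
  cohort <- structure(list(scans = scans, sequences = sequences,
                           manifest = manifest, maps = spec$maps,
                           group_params = group_params, spec = spec),
                      class = "cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (spec$render)
      for (i in seq_len(n_total))
        write_scan(scans[[i]], file.path(out_dir, paste0(scan_id[i], ".tsv")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", digits = NA)
    truth <- list(maps = spec$maps$maps, k = spec$maps$k,
                  group_params = lapply(group_params, unclass),
                  dwell_multiplier = spec$dwell_multiplier,
                  noise_sd = spec$noise_sd, seed = spec$seed)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$manifest), "scans (",
      paste(sprintf("%s=%d", names(x$spec$n_scans), x$spec$n_scans),
            collapse = ", "), ")\n")
  cat("  k =", x$maps$k, "states,", length(x$maps$parcel_labels),
      "parcels, fs =", x$spec$params$fs, "Hz,",
      x$spec$params$duration_s, "s per scan\n")
  invisible(x)
}

#' @export
print.state_maps <- function(x, ...) {
  cat("State map set: k =", x$k, "maps over", length(x$parcel_labels),
      "parcels (unit-norm rows)\n")
  cc <- x$maps %*% t(x$maps)
  cat("  max pairwise |corr|:", format(max(abs(cc[upper.tri(cc)])), digits = 3),
      "\n")
  invisible(x)
}

#' @export
print.state_sequence <- function(x, ...) {
  r <- rle(x$labels)
  cat("State sequence:", length(x$labels), "samples at", x$fs, "Hz,",
      length(r$lengths), "runs, k =", x$k,
      sprintf("(source: %s)\n", x$source))
  invisible(x)
}
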