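test_that("deterministic 2-state syntax forces strict run alternation", {
  tm <- matrix(c(0, 1, 1, 0), 2, 2)
  sq <- sample_state_sequence(
    sequence_params(tm, dwell_mean = 40, duration_s = 20, fs = 250),
    seed = 7)
  runs <- rle(sq$labels)$values
  expect_true(all(runs[-1] != runs[-length(runs)]))
  expect_setequal(unique(runs), 1:2)
})

test_that("empirical mean dwell converges to the requested mean", {
  sq <- sample_state_sequence(
    sequence_params(uniform_tm(3), dwell_mean = 100, duration_s = 600,
                    fs = 250), seed = 3)
  mean_run <- mean(rle(sq$labels)$lengths)
  expect_lt(abs(mean_run - 25) / 25, 0.05)    # 100 ms at 250 Hz = 25 samples
})

test_that("sequence generation is seed-reproducible", {
  p <- sequence_params(uniform_tm(4), dwell_mean = 80, duration_s = 30,
                       fs = 250)
  expect_identical(sample_state_sequence(p, seed = 11)$labels,
                   sample_state_sequence(p, seed = 11)$labels)
  expect_false(identical(sample_state_sequence(p, seed = 11)$labels,
                         sample_state_sequence(p, seed = 12)$labels))
})

test_that("invalid sequence parameters are rejected", {
  tm <- uniform_tm(3)
  tm[2, ] <- 0                                # absorbing state
  expect_error(sequence_params(tm), "all-zero row")
  tm2 <- uniform_tm(3)
  diag(tm2) <- 0.1                            # nonzero diagonal
  expect_error(sequence_params(tm2), "zero diagonal")
  expect_error(sequence_params(uniform_tm(3), target_hurst = 0.4), "")
  expect_error(sequence_params(uniform_tm(3), dwell_mean = -5), "")
})

test_that("generated state maps satisfy norm and correlation-cap invariants", {
  sm <- make_state_maps(7, 78, max_abs_corr = 0.5, seed = 5)
  expect_equal(unname(sqrt(rowSums(sm$maps^2))), rep(1, 7), tolerance = 1e-9)
  cc <- sm$maps %*% t(sm$maps)
  expect_lte(max(abs(cc[upper.tri(cc)])), 0.5)
  # zero-cap request with k = n_parcels: exact orthonormal construction
  sm0 <- make_state_maps(6, 6, max_abs_corr = 0, seed = 6)
  expect_equal(sm0$maps %*% t(sm0$maps), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(make_state_maps(10, 6), "cannot exceed")
  expect_error(make_state_maps(5, 40, max_abs_corr = 0.01, max_tries = 5),
               "could not satisfy")
})

test_that("noise-free single-state scans are scalar multiples of the map", {
  maps <- make_state_maps(2, 10, seed = 2)
  sq <- manual_sequence(rep(1L, 2000), fs = 250, k = 2)
  ts <- render_timeseries(sq, maps, noise_sd = 0, seed = 3)
  # every column proportional to map 1 (up to sign of the envelope sample)
  cors <- abs(cor(ts$data, maps$maps[1, ]))
  expect_gt(min(cors), 1 - 1e-8)
})

test_that("planted phase-lagged coupling yields near-unit wPLI", {
  maps <- make_state_maps(2, 8, seed = 4)
  sq <- manual_sequence(rep(1L, 5000), fs = 250, k = 2)
  cp <- coupling_spec(state = 1, i = 1, j = 2, band = "alpha",
                      phase_lag_rad = pi / 2, strength = 1)
  ts <- render_timeseries(sq, maps, coupling = cp, noise_sd = 0, seed = 5)
  z <- narrowband_analytic(ts, "alpha")
  w <- wpli(z)
  expect_gte(w[1, 2], 0.9)
})

test_that("rendering is seed-reproducible", {
  sc1 <- render_timeseries(small_scan(1)$seq, small_scan(1)$maps,
                           noise_sd = 0.3, seed = 9)
  sc2 <- render_timeseries(small_scan(1)$seq, small_scan(1)$maps,
                           noise_sd = 0.3, seed = 9)
  expect_identical(sc1$data, sc2$data)
})

test_that("empirical run-transition matrix converges to the generator's", {
  tm <- matrix(c(0, .7, .3,
                 .2, 0, .8,
                 .5, .5, 0), 3, 3, byrow = TRUE)
  sq <- sample_state_sequence(
    sequence_params(tm, dwell_mean = 20, duration_s = 250, fs = 250),
    seed = 21)
  emp <- transition_matrix(sq)$probs
  expect_gte(sq$labels |> rle() |> (\(r) length(r$values))(), 1e4)
  expect_lt(max(rowSums(abs(emp - tm))), 0.05)
})

test_that("coverage follows the stationary occupancy of the run chain", {
  tm <- matrix(c(0, .8, .2,
                 .4, 0, .6,
                 .9, .1, 0), 3, 3, byrow = TRUE)
  dwell <- c(60, 120, 90)
  sq <- sample_state_sequence(
    sequence_params(tm, dwell_mean = dwell, duration_s = 900, fs = 250),
    seed = 31)
  pi0 <- microdyn:::stationary_dist(tm)
  expected <- pi0 * dwell / sum(pi0 * dwell)
  cov <- class_stats(sq)$per_class$coverage
  expect_lt(max(abs(cov - expected)), 0.03)
})

test_that("cohort generation respects group sizes and plants dwell offsets", {
  maps <- make_state_maps(3, 8, seed = 41)
  spec <- cohort_spec(n_scans = c(A = 3, B = 4), maps = maps,
                      params = sequence_params(uniform_tm(3), dwell_mean = 60,
                                               duration_s = 120, fs = 100),
                      dwell_multiplier = c(1, 1.5), seed = 42,
                      render = FALSE)
  ch <- generate_cohort(spec)
  expect_equal(nrow(ch$manifest), 7)
  expect_equal(table(ch$manifest$group), c(A = 3L, B = 4L),
               ignore_attr = TRUE)
  durs <- vapply(ch$sequences, function(s)
    class_stats(s)$global_mean_duration_ms, 0)
  expect_gt(mean(durs[ch$manifest$group == "B"]),
            mean(durs[ch$manifest$group == "A"]))
  # identical multipliers -> no planted difference in expectation
  expect_equal(ch$group_params$A$dwell_mean * 1.5, ch$group_params$B$dwell_mean)
})

test_that("cohort generation is reproducible from the master seed", {
  maps <- make_state_maps(3, 8, seed = 41)
  spec <- cohort_spec(n_scans = c(A = 2, B = 2), maps = maps,
                      params = sequence_params(uniform_tm(3), dwell_mean = 60,
                                               duration_s = 30, fs = 100),
                      noise_sd = 0.4, seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$scans[[3]]$data, c2$scans[[3]]$data)
  expect_identical(c1$sequences[[2]]$labels, c2$sequences[[2]]$labels)
})

test_that("fractional Gaussian noise generator has the requested memory", {
  set.seed(1)
  g <- microdyn:::fgn(20000, 0.8)
  expect_equal(stats::var(g), 1, tolerance = 0.1)
  # theoretical lag-1 autocorrelation of fGn: 2^(2H-1) - 1
  expect_equal(stats::acf(g, plot = FALSE)$acf[2], 2^(2 * 0.8 - 1) - 1,
               tolerance = 0.05)
  scales <- unique(round(exp(seq(log(10), log(2000), length.out = 12))))
  expect_equal(microdyn:::dfa_exponent(g, scales), 0.8, tolerance = 0.07)
})
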