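test_that("analytic signal of a pure tone has unit envelope and linear phase", {
  fs <- 250
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  ts <- parcel_ts(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)), fs)
  z <- narrowband_analytic(ts, "alpha")
  mid <- 500:2500
  expect_equal(mean(Mod(z[1, mid])), 1, tolerance = 0.05)
  rate <- mean(diff(Arg(z[1, mid])) %% (2 * pi)) * fs / (2 * pi)
  expect_equal(rate, 10, tolerance = 0.5)
  z0 <- narrowband_analytic(parcel_ts(matrix(0, 2, 1000), fs), "alpha")
  expect_equal(max(Mod(z0)), 0)
  expect_error(narrowband_analytic(ts, c(100, 130)), "Nyquist")
})

test_that("band edges attenuate a chirp like the filter-response oracle", {
  fs <- 250
  n <- 5000
  t <- seq_len(n) / fs
  f_inst <- seq(5, 20, length.out = n)            # sweeps across the alpha band
  x <- sin(2 * pi * cumsum(f_inst) / fs)
  ts <- parcel_ts(rbind(x, x), fs)
  z <- narrowband_analytic(ts, "alpha")
  h2 <- microdyn:::butter_zero_phase_response(n, 8, 13, fs)
  freqs <- (seq_len(n) - 1) * fs / n
  amp_at <- function(f) {
    i <- which(f_inst >= f - 0.2 & f_inst <= f + 0.2)
    mean(Mod(z[1, i]))
  }
  gain_at <- function(f) h2[which.min(abs(freqs - f))]
  for (f in c(6, 10.5, 16))
    expect_equal(amp_at(f), gain_at(f), tolerance = 0.12)
})

test_that("window segmentation follows floor arithmetic and drops tails", {
  fs <- 250
  lab <- rep(c(1L, 2L), c(3125, 875))               # 12.5 s and 3.5 s
  z <- matrix(complex(real = rnorm(2 * 4000), imaginary = rnorm(2 * 4000)),
              2, 4000)
  attr(z, "fs") <- fs
  segs <- segment_windows(z, manual_sequence(lab, fs = fs, k = 3), 5)
  expect_equal(sum(segs$state == 1), 2)             # 12.5 s -> 2 windows
  expect_equal(sum(segs$state == 2), 0)             # 3.5 s -> none
  expect_equal(sum(segs$state == 3), 0)             # absent state
  expect_true(all(vapply(segs$windows, ncol, 0L) == 1250))
  # concatenation order: first window holds the first 1250 state-1 samples
  expect_identical(segs$windows[[1]][1, ], z[1, 1:1250])
})

test_that("wPLI attains its closed-form extremes and matches the formula", {
  n <- 400
  t <- seq_len(n)
  z1 <- exp(1i * 0.2 * t)
  lagged <- rbind(z1, z1 * exp(-1i * pi / 2))       # constant 90 degree lag
  expect_equal(wpli(lagged)[1, 2], 1)
  zero_lag <- rbind(z1, 2.5 * z1)                   # zero lag: denominator 0
  expect_equal(wpli(zero_lag)[1, 2], 0)
  set.seed(1)
  z <- matrix(complex(real = rnorm(5 * 200), imaginary = rnorm(5 * 200)),
              5, 200)
  got <- wpli(z)
  for (i in 1:4) for (j in (i + 1):5) {
    im <- Im(z[i, ] * Conj(z[j, ]))
    expect_equal(got[i, j], abs(mean(im)) / mean(abs(im)), tolerance = 1e-12)
  }
  expect_true(isSymmetric(got))
  expect_true(all(got >= 0 & got <= 1))
  expect_true(all(diag(got) == 0))
})

test_that("wPLI is invariant to amplitude rescaling and common rotation", {
  set.seed(2)
  z <- matrix(complex(real = rnorm(4 * 300), imaginary = rnorm(4 * 300)),
              4, 300)
  w0 <- wpli(z)
  expect_equal(wpli(z * runif(4, 0.1, 10)), w0, tolerance = 1e-12)
  expect_equal(wpli(z * exp(1i * 1.1)), w0, tolerance = 1e-12)
})

test_that("pooled wPLI equals the aggregation of its window components", {
  set.seed(3)
  wins <- lapply(c(100, 150, 80), function(n)
    matrix(complex(real = rnorm(4 * n), imaginary = rnorm(4 * n)), 4, n))
  expect_equal(microdyn:::wpli_aggregate(wins),
               wpli(do.call(cbind, wins)), tolerance = 1e-12)
})

test_that("weighted degree is the off-diagonal row sum", {
  m <- matrix(1, 78, 78)
  diag(m) <- 0
  expect_equal(weighted_degree(m), rep(77, 78))
  expect_equal(weighted_degree(matrix(0, 5, 5)), rep(0, 5))
  set.seed(4)
  s <- matrix(runif(36), 6, 6)
  s <- (s + t(s)) / 2
  expect_equal(weighted_degree(s), rowSums(s) - diag(s))
})

test_that("MVPA attains perfect, chance, and Bayes-limited accuracy", {
  set.seed(5)
  # noise-free separable class means
  mu <- matrix(rnorm(3 * 6, sd = 3), 3, 6)
  lab <- rep(1:3, each = 30)
  feats <- mu[lab, ]
  expect_equal(mvpa_classify(feats, lab, seed = 6), 1)
  # identical features for all 7 classes: accuracy equals the chance share
  same <- matrix(1, 7 * 10, 4)
  expect_equal(mvpa_classify(same, rep(1:7, each = 10), seed = 7), 1 / 7)
  # two Gaussians with Bayes error 0.2 (means 2 * qnorm(0.8) apart)
  n <- 2000
  delta <- 2 * qnorm(0.8)
  x <- matrix(rnorm(n), n, 1) + delta / 2 * rep(c(-1, 1), each = n / 2)
  acc <- mvpa_classify(x, rep(1:2, each = n / 2), seed = 8)
  expect_equal(acc, 0.8, tolerance = 0.03)
})

test_that("MVPA rejects classes too small for the fold count", {
  feats <- matrix(rnorm(24), 12, 2)
  expect_error(mvpa_classify(feats, rep(1:2, c(9, 3)), n_folds = 5),
               "fewer than")
})

test_that("permutation test pins the +1 p-value floor and rejects n_perm 0", {
  set.seed(9)
  mu <- matrix(rnorm(3 * 5, sd = 4), 3, 5)
  lab <- rep(1:3, each = 15)
  feats <- mu[lab, ] + matrix(rnorm(45 * 5, sd = 0.1), 45, 5)
  r <- permutation_test(feats, lab, n_perm = 20, seed = 10)
  expect_equal(r$accuracy, 1)
  expect_equal(r$p_value, 1 / 21)
  expect_length(r$null_accuracies, 20)
  expect_error(permutation_test(feats, lab, n_perm = 0), "n_perm")
})

test_that("edge deviation ranks pairs with ceiling count and lexicographic ties", {
  set.seed(11)
  p <- 78
  mk <- function() {
    m <- matrix(runif(p * p), p, p)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  }
  static <- mk()
  states <- setNames(lapply(1:7, function(i) mk()), 1:7)
  top <- edge_deviation(states, static, top_frac = 0.01)
  expect_equal(nrow(top), ceiling(0.01 * 7 * choose(78, 2)))  # 211 of 21021
  expect_false(is.unsorted(rev(abs(top$deviation))))
  # all-equal matrices: zero deviations, ties broken lexicographically
  same <- setNames(lapply(1:2, function(i) static), 1:2)
  t0 <- edge_deviation(same, static, top_frac = 0.001)
  expect_true(all(t0$deviation == 0))
  expect_equal(t0$state[1], 1)
  expect_equal(t0[1, c("i", "j")], data.frame(i = 1L, j = 2L),
               ignore_attr = TRUE)
})

test_that("a planted state-specific coupling is the top deviating edge", {
  maps <- make_state_maps(3, 10, seed = 12)
  sq <- sample_state_sequence(
    sequence_params(uniform_tm(3), dwell_mean = 2000, duration_s = 120,
                    fs = 100), seed = 13)
  cp <- coupling_spec(state = 2, i = 3, j = 7, band = "alpha",
                      phase_lag_rad = pi / 2, strength = 1)
  ts <- render_timeseries(sq, maps, coupling = cp, noise_sd = 0.5, seed = 14)
  sc <- state_connectivity(ts, sq, bands = "alpha", window_s = 5)
  a <- sc$bands$alpha
  # the planted pair dominates the deviation ranking: the coupled state pins
  # wPLI(3,7) at ~1 and drags the ratio-aggregated static background up, so
  # the uncoupled states deviate strongly (negatively) on exactly that edge
  top <- edge_deviation(a$state_wpli, a$static_wpli, top_frac = 0.005)
  expect_equal(sort(c(top$i[1], top$j[1])), c(3, 7))
  expect_gt(a$state_wpli[["2"]][3, 7], 0.95)
  expect_gt(a$static_wpli[3, 7], 2 * median(a$static_wpli))
})

test_that("state-specific coupling is decodable; shared coupling is not", {
  maps <- make_state_maps(3, 10, seed = 15)
  sq <- sample_state_sequence(
    sequence_params(uniform_tm(3), dwell_mean = 3000, duration_s = 240,
                    fs = 100), seed = 16)
  cps <- rbind(coupling_spec(1, 1, 2, "alpha", pi / 2, 0.9),
               coupling_spec(2, 3, 4, "alpha", pi / 2, 0.9),
               coupling_spec(3, 5, 6, "alpha", pi / 2, 0.9))
  ts <- render_timeseries(sq, maps, coupling = cps, noise_sd = 0.3, seed = 17)
  sc <- state_connectivity(ts, sq, bands = "alpha")
  a <- sc$bands$alpha
  r <- permutation_test(a$features, a$window_state, n_perm = 39, seed = 18)
  expect_gt(r$accuracy, 1 / 3 + 0.1)
  expect_lt(r$p_value, 0.05)
})
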