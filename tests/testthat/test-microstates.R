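test_that("noise-free copies of orthogonal maps are recovered perfectly", {
  sm <- make_state_maps(4, 12, max_abs_corr = 0, seed = 1)
  x <- sm$maps[rep(1:4, each = 10), ] * rep(runif(40, 0.5, 2), 12)
  m <- fit_kmeans(x, 4, restarts = 5, seed = 2)
  mm <- microdyn:::match_maps(coef(m), sm$maps)
  expect_equal(mm$mean_abs_corr, 1, tolerance = 1e-6)
  expect_equal(m$gev, 1, tolerance = 1e-9)
})

test_that("k = 1 centroid equals the first principal direction", {
  set.seed(3)
  x <- matrix(rnorm(30 * 8), 30, 8)
  m <- fit_kmeans(x, 1, restarts = 3, seed = 4)
  A <- microdyn:::normalize_rows(x)
  # oracle: leading eigenvector of the scatter of normalized maps
  v <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(m$maps[1, ] * v)), 1, tolerance = 1e-6)
})

test_that("k-means partition equals the exhaustive best bipartition by GEV", {
  # 3 parcels: demeaned maps live in a plane, so the per-cluster objective
  # (largest eigenvalue of the GFP-weighted scatter) has a closed 2x2 form
  # and all 2^19 bipartitions of 20 peaks can be enumerated exactly.
  set.seed(5)
  base <- rbind(c(1, -1, 0), c(1, 1, -2))
  x <- base[rep(1:2, each = 10), ] + matrix(rnorm(60, sd = 0.35), 20, 3)
  w <- rep(1, 20)   # equal GFP weights: partition GEV is then exactly the
                    # sum of leading eigenvalues the centroid update attains
  A <- microdyn:::normalize_rows(x)
  u <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  B <- (A %*% u) * w                          # weighted 2-d coordinates
  e11 <- B[, 1]^2; e22 <- B[, 2]^2; e12 <- B[, 1] * B[, 2]
  lam_max <- function(s11, s22, s12)
    ((s11 + s22) + sqrt((s11 - s22)^2 + 4 * s12^2)) / 2
  n_masks <- 2^19
  bits <- vapply(0:18, function(b)
    bitwAnd(0:(n_masks - 1), bitwShiftL(1L, b)) > 0, logical(n_masks))
  # peak 1 fixed in cluster A; bits give cluster-A membership of peaks 2..20
  sA11 <- e11[1] + bits %*% e11[-1]
  sA22 <- e22[1] + bits %*% e22[-1]
  sA12 <- e12[1] + bits %*% e12[-1]
  gev_all <- (lam_max(sA11, sA22, sA12) +
                lam_max(sum(e11) - sA11, sum(e22) - sA22,
                        sum(e12) - sA12)) / sum(w^2)
  best_mask <- c(TRUE, bits[which.max(gev_all), ])
  m <- fit_kmeans(x, 2, gfp = w, restarts = 30, seed = 6)
  got_A <- m$labels == m$labels[1]
  expect_identical(got_A, unname(best_mask))
  expect_equal(m$gev, max(gev_all), tolerance = 1e-9)
})

test_that("GEV matches its direct formula and attains its extremes", {
  # orthogonal zero-mean maps (Helmert contrasts), so spatial demeaning
  # preserves the orthogonality that makes the adversarial GEV exactly 0
  h <- stats::contr.helmert(10)[, 1:3]
  sm <- list(maps = t(h) / sqrt(colSums(h^2)))
  # every sample an exact (scaled, sign-flipped) copy of its map -> GEV 1
  lab <- rep(1:3, each = 5)
  x <- sm$maps[lab, ] * rep(c(-2, 1, 3), 50)[1:15]
  expect_equal(compute_gev(x, compute_gfp(t(x)), lab, sm$maps), 1,
               tolerance = 1e-9)
  # orthogonal maps assigned adversarially -> GEV 0
  wrong <- c(rep(2L, 5), rep(3L, 5), rep(1L, 5))
  expect_equal(compute_gev(x, compute_gfp(t(x)), wrong, sm$maps), 0,
               tolerance = 1e-9)
  # random instance vs direct formula evaluation
  set.seed(8)
  xr <- matrix(rnorm(12 * 10), 12, 10)
  g <- runif(12, 0.2, 3)
  labr <- sample(1:3, 12, replace = TRUE)
  An <- microdyn:::normalize_rows(xr)
  Cn <- microdyn:::normalize_rows(sm$maps)
  oracle <- sum((g * rowSums(An * Cn[labr, ]))^2) / sum(g^2)
  expect_equal(compute_gev(xr, g, labr, sm$maps), oracle, tolerance = 1e-12)
  expect_error(compute_gev(xr, rep(0, 12), labr, sm$maps), "zero")
})

test_that("kneedle matches the normalized difference-curve definition", {
  k <- 2:6
  y <- c(0.2, 0.8, 0.9, 0.95, 0.97)
  xn <- (k - 2) / 4
  yn <- (y - 0.2) / (0.97 - 0.2)
  d <- yn - xn
  expect_equal(kneedle(k, y), k[which.max(d)])
  # linear curve: difference curve identically zero -> no knee
  expect_true(is.na(kneedle(2:10, seq(0.1, 0.9, length.out = 9))))
})

test_that("model-order scan recovers planted structure on peak maps", {
  sm <- make_state_maps(4, 12, max_abs_corr = 0.4, seed = 9)
  set.seed(10)
  lab <- sample(1:4, 300, replace = TRUE)
  x <- sm$maps[lab, ] * runif(300, 0.5, 2) +
    matrix(rnorm(300 * 12, sd = 0.06), 300, 12)
  curve <- scan_k(x, 2:8, restarts = 5, seed = 11)
  expect_length(curve$gev, 7)
  expect_true(all(diff(curve$gev) > -0.01))
  # large increments up to the planted k, small after
  expect_gt(min(diff(curve$gev)[1:2]), 5 * max(diff(curve$gev)[3:6]))
  expect_equal(curve$knee, 4)
  m <- microstates(x, k = NULL, k_range = 2:8, restarts = 5, seed = 11)
  expect_equal(m$k, 4)
})

test_that("identical duplicated peak maps give GEV 1 at every k", {
  one <- microdyn:::normalize_rows(matrix(rnorm(8), 1, 8))
  x <- one[rep(1, 30), ] * runif(30, 0.5, 2)
  expect_warning(curve <- scan_k(x, 2:4, restarts = 2, seed = 12),
                 regexp = NA)
  expect_equal(curve$gev, rep(1, 3), tolerance = 1e-9)
})

test_that("backfitting follows the nearest-peak rule including ties", {
  sm <- make_state_maps(2, 6, max_abs_corr = 0, seed = 13)
  n <- 30
  x <- matrix(rnorm(6 * n, sd = 1e-3), 6, n)
  x[, 11] <- sm$maps[1, ] * 5                # peak at sample 11, state 1
  x[, 21] <- sm$maps[2, ] * 5                # peak at sample 21, state 2
  ts <- parcel_ts(x, fs = 100)
  model <- fit_kmeans(sm$maps[c(1, 1, 2, 2), ] * c(1, 2, 1, 2), 2,
                      restarts = 4, seed = 14)
  gfp <- compute_gfp(ts)
  sq <- backfit(ts, model, gfp = gfp, peak_indices = c(11L, 21L))
  s1 <- sq$labels[11]
  s2 <- sq$labels[21]
  expect_false(s1 == s2)
  expect_equal(sq$labels[1:15], rep(s1, 15))   # before first peak + nearer
  expect_equal(sq$labels[16], s1)              # equidistant tie -> earlier
  expect_equal(sq$labels[17:30], rep(s2, 14))
})

test_that("backfitting equals a brute-force nearest-peak search", {
  sc <- small_scan(3)
  model <- fit_kmeans(peak_maps(sc$ts, Inf)$maps, 4, restarts = 5, seed = 15)
  sq <- backfit(sc$ts, model)
  pk <- sq$peak_indices
  oracle <- vapply(seq_along(sq$labels), function(t) {
    d <- abs(pk - t)
    sq$peak_labels[which.min(d)]               # which.min: earliest on ties
  }, 0L)
  expect_identical(sq$labels, oracle)
})

test_that("fits are polarity-invariant under sign flips of peak maps", {
  set.seed(16)
  sm <- make_state_maps(3, 10, seed = 17)
  lab <- sample(1:3, 120, replace = TRUE)
  x <- sm$maps[lab, ] + matrix(rnorm(1200, sd = 0.1), 120, 10)
  flip <- sample(c(-1, 1), 120, replace = TRUE)
  m1 <- fit_kmeans(x, 3, restarts = 5, seed = 18)
  m2 <- fit_kmeans(x * flip, 3, restarts = 5, seed = 18)
  expect_equal(m1$gev, m2$gev, tolerance = 1e-9)
  expect_identical(m1$labels, m2$labels)
  expect_equal(unname(abs(rowSums(m1$maps * m2$maps))), rep(1, 3),
               tolerance = 1e-9)
})

test_that("permuting centroids permutes backfit labels consistently", {
  sc <- small_scan(4)
  model <- fit_kmeans(peak_maps(sc$ts, Inf)$maps, 4, restarts = 5, seed = 19)
  perm <- c(3L, 1L, 4L, 2L)
  model_p <- model
  model_p$maps <- model$maps[perm, ]
  s1 <- backfit(sc$ts, model)
  s2 <- backfit(sc$ts, model_p)
  expect_identical(perm[s2$labels], s1$labels)
  g <- compute_gfp(sc$ts)
  x <- t(sc$ts$data[, s1$peak_indices])
  expect_equal(
    compute_gev(x, g[s1$peak_indices], s1$peak_labels, model$maps),
    compute_gev(x, g[s2$peak_indices], s2$peak_labels, model_p$maps),
    tolerance = 1e-12)
})

test_that("fitted maps recover planted maps on a rendered scan", {
  sc <- small_scan(5, k = 4, p = 16, duration_s = 60, noise_sd = 0.4)
  pm <- peak_maps(bandpass(sc$ts), 800, seed = 20)
  m <- fit_kmeans(pm$maps, 4, gfp = pm$gfp, restarts = 8, seed = 21)
  mm <- microdyn:::match_maps(coef(m), sc$maps$maps)
  expect_gte(mm$mean_abs_corr, 0.9)
})
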