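#' Canonical EEG frequency bands
#'
#' @return named list of `c(lo, hi)` band edges in Hz: delta 1-4, theta 4-8,
#'   alpha 8-13, beta 13-30.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# analytic signal (zero negative frequencies) of a real vector via FFT
analytic_vector <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Narrowband analytic signal of a parcel time series
#'
#' Zero-phase bandpass into the requested band followed by the analytic
#' extension (Hilbert construction), giving instantaneous phase and amplitude
#' at every sample of every parcel.  Both steps are spectral multiplications,
#' so they share one FFT pass over all parcels.
#'
#' @param ts a `"parcel_ts"` object.
#' @param band band name (see [eeg_bands()]) or numeric `c(lo, hi)` in Hz.
#' @return complex matrix, n_parcels x n_samples, with attributes `fs` and
#'   `band`.
#' @export
narrowband_analytic <- function(ts, band = "alpha") {
  stopifnot(inherits(ts, "parcel_ts"))
  bd <- if (is.character(band)) eeg_bands()[[match.arg(band,
                                                       names(eeg_bands()))]]
        else band
  if (bd[2] >= ts$fs / 2)
    stop("band upper edge ", bd[2], " Hz is at or above Nyquist")
  n <- ncol(ts$data)
  h2 <- butter_zero_phase_response(n, bd[1], bd[2], ts$fs)
  hmask <- numeric(n)                      # analytic-extension step mask
  if (n %% 2 == 0) {
    hmask[c(1, n / 2 + 1)] <- 1
    hmask[2:(n / 2)] <- 2
  } else {
    hmask[1] <- 1
    hmask[2:((n + 1) / 2)] <- 2
  }
  xf <- stats::mvfft(t(ts$data)) * (h2 * hmask)
  z <- t(stats::mvfft(xf, inverse = TRUE)) / n
  attr(z, "fs") <- ts$fs
  attr(z, "band") <- bd
  z
}

#' Segment an analytic signal into per-state non-overlapping windows
#'
#' For each state, the samples carrying that label are concatenated in time
#' order and chopped into disjoint windows of `window_s` seconds; the residual
#' tail is dropped.  States with fewer samples than one window contribute no
#' windows.
#'
#' @param z complex analytic matrix (parcels x samples) from
#'   [narrowband_analytic()].
#' @param seq a `"state_sequence"` aligned with `z`.
#' @param window_s window length in seconds.
#' @return list with `windows` (list of complex parcel x window matrices) and
#'   `state` (integer label per window).
#' @export
segment_windows <- function(z, seq, window_s = 5) {
  stopifnot(window_s > 0, inherits(seq, "state_sequence"),
            ncol(z) == length(seq$labels))
  fs <- attr(z, "fs") %||% seq$fs
  wl <- as.integer(round(window_s * fs))
  windows <- list()
  state <- integer(0)
  for (s in seq_len(seq$k)) {
    idx <- which(seq$labels == s)
    nw <- length(idx) %/% wl
    if (nw == 0) next
    for (w in seq_len(nw)) {
      windows[[length(windows) + 1L]] <-
        z[, idx[((w - 1L) * wl + 1L):(w * wl)], drop = FALSE]
      state <- c(state, s)
    }
  }
  list(windows = windows, state = state, window_samples = wl)
}

# per-window sums of Im cross-spectrum, of its absolute value, and of the
# amplitude product (the scale against which a degenerate |Im| is judged)
wpli_components <- function(z) {
  p <- nrow(z)
  a <- Re(z)
  b <- Im(z)
  num <- matrix(0, p, p)
  den <- matrix(0, p, p)
  for (i in seq_len(p)) {
    # Im(z_i * conj(z_j)) over t, all j at once
    imS <- b[i, ] * t(a) - a[i, ] * t(b)    # n x p
    num[i, ] <- colSums(imS)
    den[i, ] <- colSums(abs(imS))
  }
  amp <- Mod(z)
  list(num = num, den = den, amp = tcrossprod(amp))
}

#' Weighted phase lag index of an analytic-signal window
#'
#' wPLI(i, j) = |mean_t Im S_ij(t)| / mean_t |Im S_ij(t)| with
#' S_ij = z_i conj(z_j) the instantaneous cross-spectrum; 0 where the
#' denominator vanishes (e.g. exactly zero-lag pairs).  Insensitive to
#' zero-lag (volume-conduction-like) coupling and to amplitude scaling.
#'
# ratio of wPLI components with the degenerate-denominator convention:
# pairs whose |Im| mass is at round-off level relative to their amplitude
# product (exactly zero-lag coupling, or zero signal) have wPLI 0
wpli_ratio <- function(num, den, amp) {
  thresh <- 1e-9 * amp
  out <- abs(num) / ifelse(den > thresh, den, 1)
  out[den <= thresh] <- 0
  diag(out) <- 0
  out
}

#' @param z complex matrix, parcels x samples (>= 2 samples).
#' @return symmetric parcels x parcels matrix in `[0, 1]` with zero diagonal.
#' @export
wpli <- function(z) {
  stopifnot(ncol(z) >= 2)
  cmp <- wpli_components(z)
  wpli_ratio(cmp$num, cmp$den, cmp$amp)
}

# wPLI pooled over a list of windows: ratio of summed components, so the
# static estimate is exactly the window-count-weighted aggregation of the
# per-state pieces
wpli_aggregate <- function(windows) {
  cmp <- lapply(windows, wpli_components)
  wpli_ratio(Reduce(`+`, lapply(cmp, `[[`, "num")),
             Reduce(`+`, lapply(cmp, `[[`, "den")),
             Reduce(`+`, lapply(cmp, `[[`, "amp")))
}

#' Weighted degree of a connectivity matrix
#'
#' @param mat symmetric connectivity matrix.
#' @return row sums excluding the diagonal.
#' @export
weighted_degree <- function(mat) {
  rowSums(mat) - diag(mat)
}

#' Microstate-segmented wPLI connectivity for one scan
#'
#' Computes, for each requested band: the analytic signal, per-state
#' 5-s-window segmentation, the per-state pooled wPLI matrix, the static
#' (all-window) wPLI matrix, and per-window weighted-degree feature vectors
#' with their state labels (the MVPA features).
#'
#' @param ts a `"parcel_ts"` scan.
#' @param seq its `"state_sequence"` labeling.
#' @param bands character vector of band names or named list of edges.
#' @param window_s window length in seconds.
#' @return an object of class `"state_connectivity"`: per band a list with
#'   `state_wpli` (list over states), `static_wpli`, `features` (windows x
#'   parcels weighted-degree matrix), `window_state`.
#' @export
state_connectivity <- function(ts, seq, bands = names(eeg_bands()),
                               window_s = 5) {
  if (is.character(bands)) {
    bands <- eeg_bands()[match.arg(bands, names(eeg_bands()),
                                   several.ok = TRUE)]
  }
  out <- list()
  for (bn in names(bands)) {
    z <- narrowband_analytic(ts, bands[[bn]])
    segs <- segment_windows(z, seq, window_s)
    if (!length(segs$windows)) {
      out[[bn]] <- list(state_wpli = NULL, static_wpli = NULL,
                        features = NULL, window_state = integer(0))
      next
    }
    cmp <- lapply(segs$windows, wpli_components)
    per_win <- lapply(cmp, function(c) wpli_ratio(c$num, c$den, c$amp))
    feats <- t(vapply(per_win, weighted_degree,
                      numeric(nrow(ts$data))))
    agg <- function(idx)
      wpli_ratio(Reduce(`+`, lapply(cmp[idx], `[[`, "num")),
                 Reduce(`+`, lapply(cmp[idx], `[[`, "den")),
                 Reduce(`+`, lapply(cmp[idx], `[[`, "amp")))
    state_wpli <- lapply(sort(unique(segs$state)),
                         function(s) agg(which(segs$state == s)))
    names(state_wpli) <- sort(unique(segs$state))
    stat <- agg(seq_along(cmp))
    out[[bn]] <- list(state_wpli = state_wpli, static_wpli = stat,
                      features = feats, window_state = segs$state)
  }
  structure(list(bands = out, window_s = window_s, scan_id = ts$scan_id),
            class = "state_connectivity")
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (c in unique(labels)) {
    idx <- which(labels == c)
    if (length(idx) < n_folds)
      stop("class ", c, " has ", length(idx), " windows, fewer than ",
           n_folds, " folds; regenerate with longer scans")
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# regularized (ridge-pooled-covariance) linear discriminant classifier;
# returns predicted labels for `test`
rlda_predict <- function(train, train_lab, test, lambda = 0.1) {
  classes <- sort(unique(train_lab))
  p <- ncol(train)
  mu <- do.call(rbind, lapply(classes, function(c)
    colMeans(train[train_lab == c, , drop = FALSE])))
  centered <- train - mu[match(train_lab, classes), , drop = FALSE]
  W <- crossprod(centered) / max(1L, nrow(train) - length(classes))
  # ridge floor keeps W invertible even for noise-free (zero-scatter) inputs
  W <- W + lambda * max(mean(diag(W)), 1e-8) * diag(p)
  Winv_mu <- solve(W, t(mu))                 # p x C
  const <- -0.5 * colSums(t(mu) * Winv_mu) +
    log(tabulate(match(train_lab, classes)) / length(train_lab))
  scores <- test %*% Winv_mu + rep(const, each = nrow(test))
  classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated MVPA decoding of microstate identity
#'
#' Stratified n-fold cross-validated accuracy of a ridge-regularized linear
#' discriminant classifier (features standardized with fold-wise training
#' statistics) predicting the window's microstate label from its
#' weighted-degree connectivity features.
#'
#' @param features windows x features numeric matrix.
#' @param labels integer state label per window.
#' @param n_folds number of folds (default 5).
#' @param lambda ridge weight on the pooled covariance (relative to its mean
#'   diagonal).
#' @param seed integer seed (fold assignment).
#' @return cross-validated accuracy in `[0, 1]`.
#' @export
mvpa_classify <- function(features, labels, n_folds = 5, lambda = 0.1,
                          seed = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  with_seed(seed, {
    fold <- stratified_folds(labels, n_folds)
    cv_accuracy(features, labels, fold, lambda)
  })
}

cv_accuracy <- function(features, labels, fold, lambda) {
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    mu <- colMeans(features[tr, , drop = FALSE])
    sd <- apply(features[tr, , drop = FALSE], 2L, stats::sd)
    sd[sd == 0] <- 1
    ztr <- sweep(sweep(features[tr, , drop = FALSE], 2L, mu), 2L, sd, "/")
    zte <- sweep(sweep(features[!tr, , drop = FALSE], 2L, mu), 2L, sd, "/")
    pred <- rlda_predict(ztr, labels[tr], zte, lambda)
    correct <- correct + sum(pred == labels[!tr])
  }
  correct / length(labels)
}

#' Permutation test of MVPA decoding accuracy
#'
#' Labels are permuted uniformly `n_perm` times and the full stratified
#' cross-validation is re-run on each permutation;
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), so p is never zero (an
#' observed accuracy above all nulls at 1000 permutations reports as
#' p < 0.001).
#'
#' @inheritParams mvpa_classify
#' @param n_perm number of label permutations (>= 1).
#' @return an object of class `"mvpa_result"`: `accuracy`,
#'   `null_accuracies`, `p_value`, `n_classes`, `n_per_class`, `n_perm`,
#'   `seed`.
#' @export
permutation_test <- function(features, labels, n_perm = 1000, n_folds = 5,
                             lambda = 0.1, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  features <- as.matrix(features)
  with_seed(seed, {
    fold <- stratified_folds(labels, n_folds)
    obs <- cv_accuracy(features, labels, fold, lambda)
    null_acc <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      pl <- sample(labels)
      pf <- stratified_folds(pl, n_folds)
      null_acc[i] <- cv_accuracy(features, pl, pf, lambda)
    }
    structure(list(accuracy = obs, null_accuracies = null_acc,
                   p_value = (1 + sum(null_acc >= obs)) / (1 + n_perm),
                   n_classes = length(unique(labels)),
                   n_per_class = table(labels), n_perm = n_perm, seed = seed),
              class = "mvpa_result")
  })
}

#' @export
print.state_connectivity <- function(x, ...) {
  cat(sprintf("State-segmented wPLI connectivity for '%s' (%g-s windows)\n",
              x$scan_id, x$window_s))
  for (bn in names(x$bands)) {
    b <- x$bands[[bn]]
    cat(sprintf("  %s: %d windows over %d states\n", bn,
                length(b$window_state), length(unique(b$window_state))))
  }
  invisible(x)
}

#' @export
print.mvpa_result <- function(x, ...) {
  cat(sprintf("MVPA: accuracy %.4f over %d classes (chance %.4f)\n",
              x$accuracy, x$n_classes, 1 / x$n_classes))
  cat(sprintf("  permutation p = %.4g (%d permutations)%s\n", x$p_value,
              x$n_perm,
              if (x$p_value <= 1 / x$n_perm) sprintf(" [p < %.3g]",
                                                     1 / x$n_perm) else ""))
  invisible(x)
}

#' Edges deviating most from static background connectivity
#'
#' Ranks every (state, edge) pair by |state wPLI - static wPLI| and returns
#' the top `ceiling(top_frac * total)` with signed deviations; ties are broken
#' by (state, i, j) lexicographic order.
#'
#' @param state_wpli named list of per-state symmetric wPLI matrices.
#' @param static_wpli the static (all-window) wPLI matrix.
#' @param top_frac fraction of (state, edge) pairs to keep (default 0.01).
#' @return data frame: `state`, `i`, `j` (i < j), `deviation`, ordered by
#'   decreasing |deviation|.
#' @export
edge_deviation <- function(state_wpli, static_wpli, top_frac = 0.01) {
  stopifnot(top_frac > 0, top_frac <= 1)
  p <- nrow(static_wpli)
  ut <- which(upper.tri(static_wpli), arr.ind = TRUE)
  rows <- lapply(seq_along(state_wpli), function(si) {
    d <- state_wpli[[si]] - static_wpli
    data.frame(state = as.integer(names(state_wpli)[si] %||% si),
               i = ut[, 1], j = ut[, 2], deviation = d[ut])
  })
  all <- do.call(rbind, rows)
  ord <- order(-abs(all$deviation), all$state, all$i, all$j)
  n_keep <- ceiling(top_frac * nrow(all))
  out <- all[ord[seq_len(n_keep)], ]
  rownames(out) <- NULL
  out
}
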