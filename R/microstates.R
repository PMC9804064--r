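#' Fit microstate maps to GFP-peak spatial maps
#'
#' The main model-fitting entry point.  Rows of `x` are spatial maps sampled
#' at GFP peaks (pooled across scans); they are spatially demeaned and
#' L2-normalized, then clustered with the polarity-invariant modified k-means:
#' assignment maximizes the squared spatial correlation with the centroids and
#' the centroid update is the first principal direction of the member maps.
#' The best of `restarts` seeded runs by global explained variance (GEV) is
#' kept.  With `k = NULL` the model order is chosen by fitting every k in
#' `k_range` and locating the knee of the GEV curve with the kneedle rule.
#'
#' @param x numeric matrix, peak samples x parcels.
#' @param k number of microstate classes, or `NULL` to select via `k_range`.
#' @param k_range candidate model orders scanned when `k` is `NULL`.
#' @param gfp GFP value of each peak sample; defaults to the spatial
#'   population SD of each row of `x`.
#' @param restarts independent k-means starts per k.
#' @param tol convergence tolerance on the change in GEV.
#' @param max_iter maximum iterations per start.
#' @param polarity_invariant if `TRUE` (default) a map and its negation are
#'   the same state (assignment by squared correlation); appropriate for
#'   source-space parcel courses whose sign is arbitrary.
#' @param sensitivity kneedle sensitivity used during model-order selection.
#' @param seed integer seed making the fit reproducible.
#' @return an object of class `"microstates"` with elements `maps` (k x
#'   n_parcels unit-norm centroid rows), `k`, `gev`, `labels` (peak
#'   assignments), `polarity_invariant`, `gev_curve` (when scanned) and
#'   `fit_meta`.
#' @seealso [predict.microstates()] for backfitting, [scan_k()], [kneedle()].
#' @examples
#' maps <- make_state_maps(4, 20, seed = 1)
#' x <- maps$maps[sample(rep(1:4, 50)), ] + matrix(rnorm(200 * 20, sd = .05), 200)
#' m <- microstates(x, k = 4, restarts = 5, seed = 1)
#' m
#' @export
microstates <- function(x, k = NULL, k_range = 2:20, gfp = NULL, restarts = 20,
                        tol = 1e-6, max_iter = 500, polarity_invariant = TRUE,
                        sensitivity = 1, seed = NULL) {
  x <- as.matrix(x)
  if (is.null(gfp)) gfp <- compute_gfp(t(x))
  if (!is.null(k)) {
    fit <- fit_kmeans(x, k, gfp = gfp, restarts = restarts, tol = tol,
                      max_iter = max_iter,
                      polarity_invariant = polarity_invariant, seed = seed)
    return(fit)
  }
  curve <- scan_k(x, k_range = k_range, gfp = gfp, restarts = restarts,
                  tol = tol, max_iter = max_iter,
                  polarity_invariant = polarity_invariant, seed = seed)
  k_sel <- curve$knee
  if (is.na(k_sel)) {
    # fallback: smallest k whose GEV increment drops below 1%
    inc <- diff(curve$gev)
    i <- which(inc < 0.01)
    k_sel <- if (length(i)) curve$k[min(i)] else max(curve$k)
    message("no knee found; falling back to k = ", k_sel,
            " (first GEV increment < 1%)")
  }
  fit <- curve$fits[[match(k_sel, curve$k)]]
  fit$gev_curve <- curve
  fit
}

# one modified-k-means start; A = demeaned unit-norm rows, w = gfp weights
kmeans_once <- function(A, w, k, tol, max_iter, polarity_invariant) {
  m <- nrow(A)
  w2sum <- sum(w^2)
  C <- A[sample.int(m, k), , drop = FALSE]
  gev_old <- -Inf
  labels <- integer(m)
  for (it in seq_len(max_iter)) {
    proj <- A %*% t(C)                       # m x k spatial correlations
    score <- if (polarity_invariant) proj^2 else proj
    labels <- max.col(score, ties.method = "first")
    fit_corr <- proj[cbind(seq_len(m), labels)]
    gev <- sum((w * fit_corr)^2) / w2sum
    # centroid update
    for (c in seq_len(k)) {
      idx <- labels == c
      if (!any(idx)) {                       # empty cluster: reseed at worst fit
        worst <- which.min(fit_corr^2)
        C[c, ] <- A[worst, ]
        labels[worst] <- c
        next
      }
      Ac <- A[idx, , drop = FALSE]
      if (polarity_invariant) {
        # first principal direction by power iteration on t(Ac) %*% Ac
        v <- C[c, ]
        for (pw in 1:8) {
          v_new <- drop(crossprod(Ac, Ac %*% v))
          nv <- sqrt(sum(v_new^2))
          if (nv == 0) break
          v_new <- v_new / nv
          if (sum(abs(v_new - v)) < 1e-10 || sum(abs(v_new + v)) < 1e-10) {
            v <- v_new
            break
          }
          v <- v_new
        }
        C[c, ] <- v
      } else {
        v <- colMeans(Ac)
        nv <- sqrt(sum(v^2))
        C[c, ] <- if (nv > 0) v / nv else A[sample.int(m, 1L), ]
      }
    }
    if (abs(gev - gev_old) < tol) break
    gev_old <- gev
  }
  proj <- A %*% t(C)
  score <- if (polarity_invariant) proj^2 else proj
  labels <- max.col(score, ties.method = "first")
  gev <- sum((w * proj[cbind(seq_len(m), labels)])^2) / w2sum
  list(maps = C, labels = labels, gev = gev, iterations = it)
}

#' Polarity-invariant modified k-means at fixed model order
#'
#' @inheritParams microstates
#' @return a `"microstates"` object (see [microstates()]).
#' @export
fit_kmeans <- function(x, k, gfp = NULL, restarts = 20, tol = 1e-6,
                       max_iter = 500, polarity_invariant = TRUE,
                       seed = NULL) {
  x <- as.matrix(x)
  m <- nrow(x)
  stopifnot(k >= 1)
  if (m < k) stop("need at least k = ", k, " peak maps, got ", m)
  if (is.null(gfp)) gfp <- compute_gfp(t(x))
  stopifnot(length(gfp) == m)
  A <- normalize_rows(x, demean = TRUE)
  if (any(attr(A, "row_norm") == 0))
    stop("spatially constant peak map(s) cannot be normalized")
  best <- NULL
  rseeds <- derive_seeds(seed, restarts)
  for (r in seq_len(restarts)) {
    run <- with_seed(rseeds[[r]],
                     kmeans_once(A, gfp, k, tol, max_iter, polarity_invariant))
    if (is.null(best) || run$gev > best$gev) best <- run
  }
  dimnames(best$maps) <- list(sprintf("state%d", seq_len(k)), colnames(x))
  structure(list(maps = best$maps, k = k, gev = best$gev,
                 labels = best$labels,
                 polarity_invariant = polarity_invariant,
                 gev_curve = NULL,
                 fit_meta = list(restarts = restarts, tol = tol,
                                 max_iter = max_iter,
                                 iterations = best$iterations, seed = seed,
                                 n_peaks = m)),
            class = "microstates")
}

#' Global explained variance of a labeling
#'
#' GEV = sum_t (gfp_t * corr(x_t, map[label_t]))^2 / sum_t gfp_t^2, where
#' corr is the spatial correlation between the (demeaned, normalized) sample
#' map and its assigned centroid; squared correlation makes it
#' polarity-invariant.
#'
#' @param x samples x parcels matrix of spatial maps.
#' @param gfp per-sample GFP values.
#' @param labels integer assignment of each sample to a centroid row.
#' @param maps k x parcels centroid matrix (any scaling; normalized here).
#' @return a fraction in `[0, 1]`.
#' @export
compute_gev <- function(x, gfp, labels, maps) {
  x <- as.matrix(x)
  stopifnot(length(gfp) == nrow(x), length(labels) == nrow(x))
  tot <- sum(gfp^2)
  if (tot == 0) stop("total GFP is zero; GEV undefined")
  A <- normalize_rows(x, demean = TRUE)
  C <- normalize_rows(maps, demean = TRUE)
  corr <- rowSums(A * C[labels, , drop = FALSE])
  sum((gfp * corr)^2) / tot
}

#' GEV as a function of model order
#'
#' Fits [fit_kmeans()] independently at each k in `k_range` and records the
#' GEV, then locates the knee with [kneedle()].  A decrease of more than 0.01
#' between successive k (possible with too few restarts) is reported as a
#' warning.
#'
#' @inheritParams microstates
#' @return an object of class `"gev_curve"`: `k`, `gev`, `knee` (selected k or
#'   `NA`), and `fits` (the per-k models).
#' @export
scan_k <- function(x, k_range = 2:20, gfp = NULL, restarts = 20, tol = 1e-6,
                   max_iter = 500, polarity_invariant = TRUE,
                   sensitivity = 1, seed = NULL) {
  stopifnot(min(k_range) >= 2)
  x <- as.matrix(x)
  if (is.null(gfp)) gfp <- compute_gfp(t(x))
  seeds <- derive_seeds(seed, length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range))
    fits[[i]] <- fit_kmeans(x, k_range[i], gfp = gfp, restarts = restarts,
                            tol = tol, max_iter = max_iter,
                            polarity_invariant = polarity_invariant,
                            seed = seeds[[i]])
  gev <- vapply(fits, `[[`, 0, "gev")
  drops <- diff(gev) < -0.01
  if (any(drops))
    warning("GEV decreased by > 0.01 at k = ",
            paste(k_range[-1][drops], collapse = ", "),
            "; consider more restarts")
  structure(list(k = k_range, gev = gev,
                 knee = kneedle(k_range, gev, sensitivity = sensitivity),
                 fits = fits),
            class = "gev_curve")
}

#' Knee-point selection on a concave performance curve
#'
#' Normalizes x and y to `[0, 1]`, forms the difference curve
#' d = y_norm - x_norm, and returns the x value at the global maximum of d,
#' provided that maximum is a local maximum clearing the sensitivity
#' threshold `sensitivity * mean(diff(x_norm))`.  Returns `NA` when no local
#' maximum clears the threshold (e.g. an exactly linear curve).
#'
#' @param k increasing x values (model orders); or a `"gev_curve"` object.
#' @param y curve values (e.g. GEV), same length as `k`.
#' @param sensitivity knee-detection sensitivity (default 1).
#' @return the selected k, or `NA` if no knee.
#' @export
kneedle <- function(k, y = NULL, sensitivity = 1) {
  if (inherits(k, "gev_curve")) {
    y <- k$gev
    k <- k$k
  }
  stopifnot(length(k) == length(y), length(k) >= 3, !is.unsorted(k))
  xn <- (k - min(k)) / (max(k) - min(k))
  ry <- max(y) - min(y)
  if (ry == 0) return(NA_integer_)
  yn <- (y - min(y)) / ry
  d <- yn - xn
  n <- length(d)
  inner <- 2:(n - 1L)
  lm_idx <- inner[d[inner] >= d[inner - 1L] & d[inner] >= d[inner + 1L]]
  thr <- sensitivity * mean(diff(xn))
  lm_idx <- lm_idx[d[lm_idx] >= thr]
  if (!length(lm_idx)) return(NA_integer_)
  k[lm_idx[which.max(d[lm_idx])]]
}

#' Backfit microstate labels to a full scan
#'
#' GFP-peak samples are labeled by the centroid at minimum distance
#' (1 - squared spatial correlation under polarity invariance, 1 - correlation
#' otherwise); every other sample inherits the label of its temporally nearest
#' peak, with ties going to the earlier peak; samples before the first or
#' after the last peak take that terminal peak's label.
#'
#' @param ts a `"parcel_ts"` scan (band-limited).
#' @param model a `"microstates"` object.
#' @param gfp optional precomputed GFP trace for `ts`.
#' @param peak_indices optional precomputed peak indices.
#' @return a `"state_sequence"` with `source = "backfit"` and the peak indices
#'   attached.
#' @export
backfit <- function(ts, model, gfp = NULL, peak_indices = NULL) {
  stopifnot(inherits(ts, "parcel_ts"), inherits(model, "microstates"))
  if (is.null(gfp)) gfp <- compute_gfp(ts)
  if (is.null(peak_indices)) peak_indices <- detect_peaks(gfp)
  if (!length(peak_indices)) stop("no GFP peaks in scan; cannot backfit")
  X <- t(ts$data[, peak_indices, drop = FALSE])
  A <- normalize_rows(X, demean = TRUE)
  C <- normalize_rows(model$maps, demean = TRUE)
  proj <- A %*% t(C)
  score <- if (model$polarity_invariant) proj^2 else proj
  peak_lab <- max.col(score, ties.method = "first")
  n <- ncol(ts$data)
  # nearest-peak propagation; ties -> earlier peak
  pos <- findInterval(seq_len(n), peak_indices)
  left <- pmax(pos, 1L)
  right <- pmin(pos + 1L, length(peak_indices))
  dl <- abs(seq_len(n) - peak_indices[left])
  dr <- abs(peak_indices[right] - seq_len(n))
  use_left <- pos >= 1L & (pos >= length(peak_indices) | dl <= dr)
  nearest <- ifelse(use_left, left, right)
  labels <- peak_lab[nearest]
  structure(list(labels = labels, fs = ts$fs, k = model$k,
                 peak_indices = peak_indices, peak_labels = peak_lab,
                 gfp = gfp, source = "backfit"),
            class = "state_sequence")
}

#' @rdname backfit
#' @param object a fitted `"microstates"` model.
#' @param newdata a `"parcel_ts"` scan to label.
#' @param ... passed on to [backfit()].
#' @export
predict.microstates <- function(object, newdata, ...) {
  backfit(newdata, object, ...)
}

#' @export
print.microstates <- function(x, ...) {
  cat("Microstate model: k =", x$k, "states over", ncol(x$maps),
      "parcels\n")
  cat(sprintf("  GEV = %.4f (%s, %d peak maps, %d restarts)\n", x$gev,
              if (x$polarity_invariant) "polarity-invariant" else
                "polarity-sensitive",
              x$fit_meta$n_peaks, x$fit_meta$restarts))
  if (!is.null(x$gev_curve))
    cat("  model order selected by kneedle over k =",
        min(x$gev_curve$k), "..", max(x$gev_curve$k), "\n")
  invisible(x)
}

#' @export
summary.microstates <- function(object, ...) {
  cnt <- tabulate(object$labels, object$k)
  out <- list(k = object$k, gev = object$gev,
              peak_counts = cnt,
              peak_fraction = cnt / length(object$labels),
              gev_curve = object$gev_curve,
              fit_meta = object$fit_meta)
  class(out) <- "summary.microstates"
  out
}

#' @export
print.summary.microstates <- function(x, ...) {
  cat("Microstate model summary\n")
  cat(sprintf("  k = %d, GEV = %.4f\n", x$k, x$gev))
  tab <- data.frame(state = seq_len(x$k), n_peaks = x$peak_counts,
                    fraction = round(x$peak_fraction, 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$gev_curve) && !is.na(x$gev_curve$knee))
    cat("  kneedle-selected k =", x$gev_curve$knee, "\n")
  invisible(x)
}

#' @export
coef.microstates <- function(object, ...) object$maps

#' Plot a fitted microstate model or its GEV curve
#'
#' With a scanned model the GEV-vs-k curve is drawn and the selected knee
#' marked; otherwise the centroid maps are shown as parcel profiles.
#'
#' @param x a `"microstates"` object.
#' @param ... passed to the underlying plotting call.
#' @export
plot.microstates <- function(x, ...) {
  if (!is.null(x$gev_curve)) {
    plot(x$gev_curve, ...)
  } else {
    graphics::matplot(t(x$maps), type = "l", lty = 1,
                      xlab = "parcel", ylab = "map weight",
                      main = sprintf("Microstate maps (k = %d)", x$k), ...)
  }
  invisible(x)
}

#' @export
plot.gev_curve <- function(x, ...) {
  plot(x$k, x$gev, type = "b", pch = 16, xlab = "number of states k",
       ylab = "GEV", main = "Global explained variance vs model order", ...)
  if (!is.na(x$knee)) {
    graphics::points(x$knee, x$gev[match(x$knee, x$k)], pch = 3, cex = 2,
                     col = "red")
    graphics::mtext(sprintf("knee at k = %d", x$knee), side = 3, line = 0)
  }
  invisible(x)
}

#' Simulate scans from a fitted microstate model
#'
#' Renders synthetic parcel time series whose spatial states are the fitted
#' centroid maps, using the semi-Markov sequence generator; useful for
#' parametric-bootstrap style checks of the full pipeline.
#'
#' @param object a `"microstates"` object.
#' @param nsim number of scans.
#' @param seed integer seed.
#' @param params a [sequence_params()] object (defaults to uniform
#'   off-diagonal syntax, 100 ms dwell, 60 s at 250 Hz).
#' @param noise_sd additive noise SD (see [render_timeseries()]).
#' @param ... unused.
#' @return list of `"parcel_ts"` scans with the generating sequences attached
#'   as attribute `"sequences"`.
#' @export
simulate.microstates <- function(object, nsim = 1, seed = NULL, params = NULL,
                                 noise_sd = 0.5, ...) {
  k <- object$k
  if (is.null(params)) {
    tm <- matrix(1 / (k - 1), k, k)
    diag(tm) <- 0
    params <- sequence_params(tm, dwell_mean = 100, duration_s = 60, fs = 250)
  }
  maps <- structure(list(maps = object$maps, k = k,
                         parcel_labels = colnames(object$maps) %||%
                           sprintf("P%03d", seq_len(ncol(object$maps)))),
                    class = "state_maps")
  seeds <- derive_seeds(seed, 2L * nsim)
  seqs <- vector("list", nsim)
  scans <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    seqs[[i]] <- sample_state_sequence(params, seed = seeds[[2L * i - 1L]])
    scans[[i]] <- render_timeseries(seqs[[i]], maps, noise_sd = noise_sd,
                                    seed = seeds[[2L * i]],
                                    scan_id = sprintf("sim%03d", i))
  }
  attr(scans, "sequences") <- seqs
  scans
}
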