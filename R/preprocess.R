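#' Parcel time-series container
#'
#' @param data n_parcels x n_samples numeric matrix (rows = parcels).
#' @param fs sampling rate in Hz.
#' @param parcel_labels optional parcel names (defaults to P001, P002, ...).
#' @param scan_id scan identifier.
#' @param group group label (e.g. "MCS", "VS") or NA.
#' @return an object of class `"parcel_ts"`.
#' @export
parcel_ts <- function(data, fs, parcel_labels = NULL, scan_id = "scan",
                      group = NA) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 2, fs > 0, !anyNA(data))
  if (is.null(parcel_labels))
    parcel_labels <- sprintf("P%03d", seq_len(nrow(data)))
  stopifnot(length(parcel_labels) == nrow(data))
  rownames(data) <- parcel_labels
  structure(list(data = data, fs = fs, parcel_labels = parcel_labels,
                 scan_id = scan_id, group = group),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("Parcel time series '%s': %d parcels x %d samples at %g Hz",
              x$scan_id, nrow(x$data), ncol(x$data), x$fs))
  if (!is.na(x$group)) cat(" [group ", x$group, "]", sep = "")
  cat("\n")
  invisible(x)
}

# squared-magnitude response of a digital 4th-order Butterworth bandpass at
# the n FFT bin frequencies (the exact zero-phase forward-backward response)
butter_zero_phase_response <- function(n, lo, hi, fs) {
  ny <- fs / 2
  stopifnot(lo > 0, lo < hi, hi < ny)
  bf <- signal::butter(4, c(lo, hi) / ny, type = "pass")
  nh <- n %/% 2
  w <- 2 * pi * (0:nh) / n
  ew <- exp(-1i * outer(w, 0:(length(bf$b) - 1L)))
  h <- as.vector(ew %*% bf$b) / as.vector(ew %*% bf$a)
  h2 <- Mod(h)^2
  # mirror onto negative frequencies
  c(h2, rev(h2[2:(n - nh)]))
}

# zero-phase Butterworth bandpass of the columns-of-time matrix x (signals in
# rows), applied in the frequency domain so all rows share two FFT passes
bandpass_mat <- function(x, lo, hi, fs) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  n <- ncol(x)
  h2 <- butter_zero_phase_response(n, lo, hi, fs)
  xf <- stats::mvfft(t(x)) * h2
  t(Re(stats::mvfft(xf, inverse = TRUE))) / n
}

bandpass_vector <- function(x, lo, hi, fs) {
  as.numeric(bandpass_mat(matrix(x, nrow = 1L), lo, hi, fs))
}

#' Zero-phase Butterworth bandpass filter
#'
#' Band-limits every parcel with a zero-phase 4th-order Butterworth: the
#' filter's forward-backward squared-magnitude response is applied in the
#' frequency domain, which is phase-free by construction and lets all parcels
#' share a single FFT pass.  (The boundary handling is circular, appropriate
#' for the long resting-state records this package targets.)
#'
#' @param ts a `"parcel_ts"` object.
#' @param lo,hi band edges in Hz; `hi` must be below Nyquist.
#' @return a filtered `"parcel_ts"` of the same shape.
#' @export
bandpass <- function(ts, lo = 1, hi = 30) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (hi >= ts$fs / 2)
    stop("upper edge ", hi, " Hz is at or above Nyquist (", ts$fs / 2, " Hz)")
  out <- ts
  out$data <- bandpass_mat(ts$data, lo, hi, ts$fs)
  rownames(out$data) <- ts$parcel_labels
  out
}

#' Global field power of a parcel time series
#'
#' GFP at sample t is the spatial (across-parcel) population standard
#' deviation of the parcel values, i.e. the RMS after removing the spatial
#' mean.  `method = "rms"` skips the spatial demeaning.
#'
#' @param ts a `"parcel_ts"` object or a parcels x samples matrix.
#' @param method `"sd"` (spatial-mean removed, default) or `"rms"`.
#' @return numeric vector of nonnegative per-sample GFP values.
#' @export
compute_gfp <- function(ts, method = c("sd", "rms")) {
  method <- match.arg(method)
  x <- if (inherits(ts, "parcel_ts")) ts$data else as.matrix(ts)
  msq <- colMeans(x^2)
  v <- if (method == "sd") msq - colMeans(x)^2 else msq
  sqrt(pmax(v, 0))
}

#' Strict local maxima of a GFP trace
#'
#' A peak is a sample strictly above both neighbours; plateaus count once, at
#' their leftmost sample; the first and last samples are never peaks.
#'
#' @param values numeric vector (length >= 3).
#' @return integer vector of peak indices (1-based), strictly increasing.
#' @export
detect_peaks <- function(values) {
  stopifnot(length(values) >= 3)
  r <- rle(values)
  nr <- length(r$values)
  if (nr < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-nr]))
  inner <- 2:(nr - 1L)
  is_peak <- r$values[inner] > r$values[inner - 1L] &
    r$values[inner] > r$values[inner + 1L]
  starts[inner][is_peak]
}

#' Random subsample of GFP peaks
#'
#' Uniform sample without replacement of `min(n, length(peak_indices))`
#' peaks, returned sorted.  A warning is raised when fewer than `n` peaks are
#' available (all are returned).
#'
#' @param peak_indices integer vector of peak positions.
#' @param n number of peaks requested (>= 1).
#' @param seed integer seed, or `NULL`.
#' @return sorted integer vector.
#' @export
sample_peaks <- function(peak_indices, n, seed = NULL) {
  stopifnot(n >= 1)
  if (length(peak_indices) == 0) stop("no peaks to sample from")
  if (length(peak_indices) <= n) {
    if (length(peak_indices) < n)
      warning("only ", length(peak_indices), " peaks available; requested ", n)
    return(sort(peak_indices))
  }
  with_seed(seed, sort(sample(peak_indices, n)))
}

#' Extract (optionally subsampled) GFP-peak spatial maps from a scan
#'
#' Convenience wrapper: computes the GFP trace, detects its strict local
#' maxima, optionally subsamples `n_peaks` of them, and returns the spatial
#' maps at those samples together with their GFP values.
#'
#' @param ts a `"parcel_ts"` object (already band-limited).
#' @param n_peaks peaks to sample per scan (`Inf` keeps all).
#' @param seed integer seed for the subsampling.
#' @param method GFP definition passed to [compute_gfp()].
#' @return list with `maps` (n_peaks x n_parcels matrix, rows = peak samples),
#'   `gfp` (their GFP values), `peak_indices`, and `gfp_trace`.
#' @export
peak_maps <- function(ts, n_peaks = 5000, seed = NULL, method = "sd") {
  stopifnot(inherits(ts, "parcel_ts"))
  g <- compute_gfp(ts, method = method)
  pk <- detect_peaks(g)
  if (is.finite(n_peaks)) pk <- sample_peaks(pk, n_peaks, seed = seed)
  list(maps = t(ts$data[, pk, drop = FALSE]), gfp = g[pk],
       peak_indices = pk, gfp_trace = g)
}
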