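#' Run-length encoding of a state sequence
#'
#' @param seq a `"state_sequence"` or integer label vector.
#' @return data frame with columns `label`, `start` (1-based), `length`;
#'   concatenating the runs reconstructs the sequence.
#' @export
run_length_encode <- function(seq) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else seq
  stopifnot(length(labels) >= 1)
  r <- rle(labels)
  n <- length(r$lengths)
  data.frame(label = r$values,
             start = cumsum(c(1L, r$lengths[-n])),
             length = r$lengths)
}

#' Global and per-class microstate sequence statistics
#'
#' Per class: mean duration (mean run length in ms), coverage (fraction of
#' samples), occurrence (runs per second).  Globally: the mean duration over
#' all runs.  Classes absent from the sequence get coverage 0, occurrence 0
#' and `NA` duration, and are flagged in the `present` column.
#'
#' @param seq a `"state_sequence"` (or integer labels; then `fs` is required).
#' @param k number of classes (defaults to `seq$k`).
#' @param fs sampling rate in Hz, used to convert to ms and per-second rates.
#' @param exclude_boundary_runs drop the first and last (scan-truncated) runs
#'   from the duration and occurrence tallies.
#' @return an object of class `"sequence_stats"`: `per_class` data frame
#'   (class, duration_ms, coverage, occurrence, present),
#'   `global_mean_duration_ms`, `n_runs`, `fs`.
#' @export
class_stats <- function(seq, k = NULL, fs = NULL,
                        exclude_boundary_runs = FALSE) {
  if (inherits(seq, "state_sequence")) {
    labels <- seq$labels
    fs <- fs %||% seq$fs
    k <- k %||% seq$k
  } else labels <- seq
  stopifnot(!is.null(fs), !is.null(k), all(labels >= 1), all(labels <= k))
  n <- length(labels)
  runs <- run_length_encode(labels)
  cov_samples <- vapply(seq_len(k),
                        function(c) sum(runs$length[runs$label == c]), 0)
  drop_idx <- if (exclude_boundary_runs && nrow(runs) > 2)
    c(1L, nrow(runs))
  rr <- if (is.null(drop_idx)) runs else runs[-drop_idx, , drop = FALSE]
  dur <- vapply(seq_len(k), function(c) {
    l <- rr$length[rr$label == c]
    if (length(l)) mean(l) * 1000 / fs else NA_real_
  }, 0)
  occ <- vapply(seq_len(k), function(c) sum(rr$label == c), 0) / (n / fs)
  per_class <- data.frame(class = seq_len(k),
                          duration_ms = dur,
                          coverage = cov_samples / n,
                          occurrence = occ,
                          present = cov_samples > 0)
  structure(list(per_class = per_class,
                 global_mean_duration_ms = mean(rr$length) * 1000 / fs,
                 n_runs = nrow(runs), fs = fs, k = k),
            class = "sequence_stats")
}

#' @export
print.sequence_stats <- function(x, ...) {
  cat(sprintf("Sequence statistics: %d runs, global mean duration %.1f ms\n",
              x$n_runs, x$global_mean_duration_ms))
  print(transform(x$per_class, duration_ms = round(duration_ms, 1),
                  coverage = round(coverage, 4),
                  occurrence = round(occurrence, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Microstate syntax (transition) matrix of a sequence
#'
#' Counts transitions between successive runs (self-transitions are
#' structurally impossible, so the diagonal is zero) and row-normalizes to
#' probabilities.  Rows with no outgoing transitions stay zero and are
#' reported in `empty_rows`.
#'
#' @param seq a `"state_sequence"` or integer label vector.
#' @param k number of classes.
#' @return an object of class `"syntax_matrix"`: `counts` (k x k integer),
#'   `probs` (row-stochastic where defined, zero diagonal), `n_transitions`,
#'   `empty_rows`.
#' @export
transition_matrix <- function(seq, k = NULL) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else seq
  if (inherits(seq, "state_sequence")) k <- k %||% seq$k
  stopifnot(!is.null(k))
  r <- rle(labels)$values
  if (length(r) < 2) stop("need at least 2 runs to form transitions")
  counts <- table(factor(r[-length(r)], levels = seq_len(k)),
                  factor(r[-1], levels = seq_len(k)))
  counts <- matrix(as.integer(counts), k, k)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  structure(list(counts = counts, probs = probs,
                 n_transitions = length(r) - 1L,
                 empty_rows = which(rs == 0)),
            class = "syntax_matrix")
}

#' @export
print.syntax_matrix <- function(x, ...) {
  cat("Syntax matrix:", x$n_transitions, "transitions\n")
  print(round(x$probs, 3))
  if (length(x$empty_rows))
    cat("  rows with no outgoing transitions:",
        paste(x$empty_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Group-level syntax matrix
#'
#' Unweighted element-wise mean of per-scan transition probability matrices
#' (so long scans do not dominate).  Rows that were empty in any constituent
#' matrix are flagged.
#'
#' @param matrices list of `"syntax_matrix"` objects with a common k.
#' @return a `"syntax_matrix"` whose `probs` is the mean; `counts` is the sum.
#' @export
group_syntax <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  k <- nrow(matrices[[1]]$probs)
  for (m in matrices)
    if (nrow(m$probs) != k) stop("syntax matrices have mixed k")
  probs <- Reduce(`+`, lapply(matrices, `[[`, "probs")) / length(matrices)
  counts <- Reduce(`+`, lapply(matrices, `[[`, "counts"))
  structure(list(counts = counts, probs = probs,
                 n_transitions = sum(vapply(matrices, `[[`, 0L,
                                            "n_transitions")),
                 empty_rows = sort(unique(unlist(lapply(matrices, `[[`,
                                                        "empty_rows"))))),
            class = "syntax_matrix")
}

# DFA fluctuation exponent of a numeric series: log-log slope of the RMS
# linearly-detrended fluctuation of the integrated profile over window sizes.
dfa_exponent <- function(x, scales) {
  y <- cumsum(x - mean(x))
  n_tot <- length(y)
  f <- vapply(scales, function(n) {
    m <- n_tot %/% n
    seg <- matrix(y[seq_len(n * m)], n, m)
    t1 <- seq_len(n)
    st <- sum(t1)
    stt <- sum(t1^2) - st^2 / n
    sy <- colSums(seg)
    sty <- colSums(seg * t1)
    syy <- colSums(seg^2)
    b <- (sty - st * sy / n) / stt          # per-segment slope
    ss_res <- syy - sy^2 / n - b^2 * stt    # residual sum of squares
    sqrt(mean(pmax(ss_res, 0)) / n)
  }, 0)
  keep <- f > 0
  if (sum(keep) < 2) return(NA_real_)
  stats::coef(stats::lm(log(f[keep]) ~ log(scales[keep])))[[2]]
}

# all unordered bipartitions of 1..k into two nonempty sets (as logical
# membership of the side containing state 1): 2^(k-1) - 1 of them
all_bipartitions <- function(k) {
  out <- list()
  for (code in seq_len(2^(k - 1) - 1)) {
    side <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(k - 2)))))
    out[[length(out) + 1L]] <- side
  }
  out
}

#' Hurst exponent of a microstate label sequence
#'
#' Embeds the symbolic sequence as random walks: for each bipartition of the
#' label set into two groups, samples map to +1/-1 increments; the Hurst
#' exponent of each walk is estimated by detrended fluctuation analysis
#' (log-log regression of the linearly detrended fluctuation against window
#' size over `scale_range`), and the mean over bipartitions is returned.  All
#' 2^(k-1) - 1 bipartitions are used for k <= 8, otherwise a seeded sample of
#' `n_bipartitions`.
#'
#' By default the window range adapts to the sequence: the smallest window is
#' 50 times the mean run length (but at least 10 samples) and the largest a
#' tenth of the sequence.  Below roughly 50 mean dwells the walk is in the
#' ballistic crossover regime imposed by the runs themselves -- the local
#' slope there reflects dwell length, not memory -- so including smaller
#' windows would bias every estimate toward 1 regardless of long-range
#' dependence.
#'
#' @param seq a `"state_sequence"` or integer label vector.
#' @param k number of classes.
#' @param scale_range smallest and largest DFA window in samples; `NULL`
#'   (default) uses the adaptive range above.  The largest window is always
#'   capped at a tenth of the sequence length.
#' @param n_scales number of log-spaced window sizes.
#' @param n_bipartitions bipartitions sampled when k > 8.
#' @param seed integer seed for the bipartition sample.
#' @return estimated Hurst exponent (0.5 for memoryless sequences, > 0.5 for
#'   persistent long-range-dependent ones).
#' @export
hurst_exponent <- function(seq, k = NULL, scale_range = NULL,
                           n_scales = 10, n_bipartitions = 63, seed = NULL) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else seq
  if (inherits(seq, "state_sequence")) k <- k %||% seq$k
  k <- k %||% max(labels)
  n <- length(labels)
  if (length(unique(labels)) < 2)
    stop("constant label sequence: Hurst exponent undefined")
  if (is.null(scale_range)) {
    mean_run <- n / length(rle(labels)$lengths)
    scale_range <- c(max(10, 50 * mean_run), n / 10)
  }
  hi <- min(scale_range[2], n %/% 10)
  if (hi <= scale_range[1])
    stop("sequence too short for scale_range (need length >= 10 * min scale)")
  scales <- unique(round(exp(seq(log(scale_range[1]), log(hi),
                                 length.out = n_scales))))
  parts <- if (k <= 8) all_bipartitions(k) else
    with_seed(seed, {
      pool <- all_bipartitions_sample(k, n_bipartitions)
      pool
    })
  h <- vapply(parts, function(side) {
    x <- ifelse(side[labels], 1, -1)
    if (length(unique(x)) < 2) return(NA_real_)
    dfa_exponent(x, scales)
  }, 0)
  h <- h[!is.na(h)]
  if (!length(h)) stop("all bipartitions degenerate; Hurst undefined")
  mean(h)
}

# seeded sample of distinct bipartition codes for large k
all_bipartitions_sample <- function(k, n) {
  codes <- sample.int(2^(k - 1) - 1, min(n, 2^(k - 1) - 1))
  lapply(codes, function(code)
    c(TRUE, as.logical(bitwAnd(code, 2^(0:(k - 2))))))
}

# one random shuffle of the run-label multiset with no two adjacent runs
# equal: count-weighted sequential construction (next label drawn with
# probability proportional to its remaining count among labels differing from
# the previous one), restarting on the rare dead end.  Plain rejection
# sampling of full permutations is infeasible here -- its acceptance
# probability decays like (1 - 1/k)^n -- while this construction is the
# standard practical surrogate and matches it closely for balanced multisets.
shuffle_runs <- function(r, max_attempts = 1000L) {
  labs <- sort(unique(r))
  counts0 <- tabulate(match(r, labs))
  n <- length(r)
  if (max(counts0) > (n + 1L) %/% 2L) return(NULL)  # infeasible multiset
  for (a in seq_len(max_attempts)) {
    counts <- counts0
    out <- integer(n)
    prev <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      avail <- counts
      if (prev > 0L) avail[prev] <- 0L
      tot <- sum(avail)
      if (tot == 0L) {
        ok <- FALSE
        break
      }
      pick <- sample.int(length(labs), 1L, prob = avail / tot)
      out[i] <- labs[pick]
      counts[pick] <- counts[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  NULL
}

#' Surrogate test for non-random microstate syntax
#'
#' The null model preserves the multiset of run labels but shuffles their
#' order uniformly subject to no two adjacent runs being equal (rejection
#' sampling).  For each transition cell, the one-sided p-value is
#' (1 + #\{surrogate prob >= observed prob\}) / (1 + n_surrogates); the
#' two-sided value is twice the smaller tail, capped at 1.
#'
#' @param seq a `"state_sequence"` or integer label vector.
#' @param k number of classes.
#' @param n_surrogates number of surrogate sequences.
#' @param seed integer seed.
#' @return an object of class `"syntax_test"`: `observed` (probs),
#'   `p_greater`, `p_less`, `p_two_sided` (k x k matrices), `n_surrogates`.
#' @export
syntax_surrogate_test <- function(seq, k = NULL, n_surrogates = 1000,
                                  seed = NULL) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else seq
  if (inherits(seq, "state_sequence")) k <- k %||% seq$k
  stopifnot(!is.null(k), n_surrogates >= 1)
  r <- rle(labels)$values
  if (length(r) < 2) stop("need at least 2 runs")
  obs <- transition_matrix(labels, k)$probs
  with_seed(seed, {
    ge <- matrix(0L, k, k)
    le <- matrix(0L, k, k)
    for (s in seq_len(n_surrogates)) {
      sh <- shuffle_runs(r)
      if (is.null(sh))
        stop("rejection sampling failed: run-label multiset admits too few ",
             "valid arrangements")
      ps <- transition_matrix(sh, k)$probs  # sh has no adjacent repeats
      ge <- ge + (ps >= obs)
      le <- le + (ps <= obs)
    }
    p_greater <- (1 + ge) / (1 + n_surrogates)
    p_less <- (1 + le) / (1 + n_surrogates)
    structure(list(observed = obs, p_greater = p_greater, p_less = p_less,
                   p_two_sided = pmin(2 * pmin(p_greater, p_less), 1),
                   n_surrogates = n_surrogates),
              class = "syntax_test")
  })
}

#' @export
print.syntax_test <- function(x, ...) {
  cat("Syntax surrogate test (", x$n_surrogates, " surrogates)\n", sep = "")
  cat("two-sided p-values:\n")
  print(round(x$p_two_sided, 4))
  invisible(x)
}
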