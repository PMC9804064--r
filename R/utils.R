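# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses (and advances) the
# current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit seed derivation from a master seed.  Draws `n`
# integers below 2^31 from a stream seeded by `seed`, so sub-tasks are
# independently reproducible.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Exact fractional Gaussian noise by Davies-Harte circulant embedding.
# Returns n increments of fractional Brownian motion with Hurst index `hurst`,
# standard normal marginals (unit variance).
fgn <- function(n, hurst) {
  stopifnot(n >= 1, hurst > 0, hurst < 1)
  if (n == 1L) return(stats::rnorm(1L))
  m <- n - 1L
  k <- 0:m
  g <- 0.5 * ((k + 1)^(2 * hurst) - 2 * k^(2 * hurst) + abs(k - 1)^(2 * hurst))
  circ <- c(g, g[m:2])                       # length 2m circulant first row
  lam <- Re(stats::fft(circ))
  lam[lam < 0] <- 0                          # guard tiny negative round-off
  M <- length(circ)
  half <- M / 2
  w <- complex(length.out = M)
  w[1] <- sqrt(lam[1]) * stats::rnorm(1)
  w[half + 1] <- sqrt(lam[half + 1]) * stats::rnorm(1)
  u <- stats::rnorm(half - 1)
  v <- stats::rnorm(half - 1)
  idx <- 2:half
  w[idx] <- sqrt(lam[idx] / 2) * complex(real = u, imaginary = v)
  w[M + 2 - idx] <- Conj(w[idx])
  x <- Re(stats::fft(w, inverse = TRUE)) / sqrt(M)
  x[seq_len(n)]
}

# Spatially demean (across parcels) and L2-normalize the rows of a maps/sample
# matrix; rows with zero variance get norm 0 and are returned as zero rows.
normalize_rows <- function(x, demean = TRUE) {
  x <- as.matrix(x)
  if (demean) x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  ok <- nrm > 0
  x[ok, ] <- x[ok, , drop = FALSE] / nrm[ok]
  x[!ok, ] <- 0
  attr(x, "row_norm") <- nrm
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Optimal one-to-one matching between two map sets maximizing total |corr|.
# Exhaustive over permutations (intended for k <= 8).
match_maps <- function(fitted, truth) {
  stopifnot(nrow(fitted) == nrow(truth))
  k <- nrow(fitted)
  a <- normalize_rows(fitted)
  b <- normalize_rows(truth)
  cm <- abs(a %*% t(b))
  perms <- permutations_of(k)
  best <- NULL
  best_sum <- -Inf
  for (p in perms) {
    s <- sum(cm[cbind(seq_len(k), p)])
    if (s > best_sum) {
      best_sum <- s
      best <- p
    }
  }
  list(assignment = best, abs_corr = cm[cbind(seq_len(k), best)],
       mean_abs_corr = best_sum / k)
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    sub <- permutations_of(k - 1L)
    rest <- seq_len(k)[-i]
    for (s in sub) out[[length(out) + 1L]] <- c(i, rest[s])
  }
  out
}
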