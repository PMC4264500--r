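# internal helpers

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.  All stochastic operations in the package funnel through
# this so that identical (config, seed) pairs are bit-reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

rms <- function(x) sqrt(mean(x^2))

# causal moving average over `n` samples; at the start of the series the
# window grows sample by sample (average over the samples available so far)
causal_ma <- function(x, n) {
  cs <- cumsum(x)
  m <- length(x)
  out <- numeric(m)
  if (m <= n) return(cs / seq_len(m))
  head_idx <- seq_len(n)
  out[head_idx] <- cs[head_idx] / head_idx
  idx <- (n + 1L):m
  out[idx] <- (cs[idx] - cs[idx - n]) / n
  out
}

# centred (zero-phase) moving average, window of ~n samples; windows
# shrink at the edges.  cumsum-based, O(length(x)).
centred_ma <- function(x, n) {
  if (n <= 1L) return(x)
  m <- length(x)
  half <- floor(n / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(m) - half, 1L)
  hi <- pmin(seq_len(m) + half, m)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# columnwise moving averages (same semantics as causal_ma / centred_ma)
causal_ma_mat <- function(X, n) {
  m <- nrow(X)
  cs <- apply(X, 2, cumsum)
  den <- pmin(seq_len(m), n)
  if (m > n) {
    shifted <- rbind(matrix(0, n, ncol(X)),
                     cs[seq_len(m - n), , drop = FALSE])
    (cs - shifted) / den
  } else cs / den
}

centred_ma_mat <- function(X, n) {
  if (n <= 1L) return(X)
  m <- nrow(X)
  half <- floor(n / 2)
  cs <- rbind(0, apply(X, 2, cumsum))
  lo <- pmax(seq_len(m) - half, 1L)
  hi <- pmin(seq_len(m) + half, m)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# type-7 quantiles of every column of a matrix, via partial sorting
col_quantiles <- function(X, probs) {
  n <- nrow(X)
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  g <- h - lo
  part <- sort(unique(c(lo, pmin(lo + 1L, n))))
  out <- matrix(NA_real_, length(probs), ncol(X))
  for (j in seq_len(ncol(X))) {
    s <- sort.int(X[, j], partial = part)
    out[, j] <- s[lo] * (1 - g) + s[pmin(lo + 1L, n)] * g
  }
  out
}
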