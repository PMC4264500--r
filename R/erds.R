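#' Overlapping band grid for ERD/ERS maps
#'
#' Default: 35 overlapping bands covering 6-40 Hz, 2 Hz wide with a 1 Hz
#' step, i.e. band i = [6 + i, 8 + i] Hz for i = 0..34.
#'
#' @param low,high lowest band edge and highest band start, Hz.
#' @param width band width, Hz.
#' @param step band step, Hz.
#' @return A data.frame of class `band_grid` with columns `low`, `high`
#'   and `center`.
#' @export
band_grid <- function(low = 6, high = 40, width = 2, step = 1) {
  lo <- seq(low, high, by = step)
  structure(data.frame(low = lo, high = lo + width, center = lo + width / 2),
            class = c("band_grid", "data.frame"))
}

# design one band-pass; order 4 Butterworth (8-pole band-pass)
bp_filter <- function(band, fs, order = 4) {
  ny <- fs / 2
  if (band[1] <= 0 || band[2] >= ny)
    stopf("band [%g, %g] Hz outside (0, %g) at fs = %g", band[1], band[2],
          ny, fs)
  signal::butter(order, band / ny, "pass")
}

#' Per-trial band-power time courses
#'
#' The classic ERD/ERS power estimate: band-pass filter, square, moving
#' average.  Offline (default) the filter is applied forward-backward
#' (zero phase) and the smoothing window is centred; `causal = TRUE`
#' switches both to forward-only operation for online use.
#'
#' @param epochs an `epoch_set`; rejected trials are excluded.
#' @param band numeric length-2 band edges, Hz (inside (0, fs/2)).
#' @param smooth_s moving-average window, seconds (0 disables smoothing).
#' @param causal use causal filtering and a trailing (causal) moving
#'   average.
#' @return Array trials x channels x samples of non-negative power
#'   (microvolts squared); the trial dimension covers unrejected trials,
#'   recorded in the `trials` attribute.
#' @export
band_power_trials <- function(epochs, band, smooth_s = 0.25,
                              causal = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- which(!epochs$rejected)
  d <- dim(epochs$data)
  bt <- bp_filter(band, epochs$fs)
  n_sm <- round(smooth_s * epochs$fs)
  arr <- epochs$data[keep, , , drop = FALSE]
  X <- matrix(aperm(arr, c(3, 1, 2)), nrow = d[3])  # cols: (trial, channel)
  P <- filter_mat(bt, X, causal = causal)^2
  if (n_sm > 1)
    P <- if (causal) causal_ma_mat(P, n_sm) else centred_ma_mat(P, n_sm)
  out <- aperm(array(P, c(d[3], length(keep), d[2])), c(2, 3, 1))
  dimnames(out) <- list(NULL, epochs$labels, NULL)
  attr(out, "trials") <- keep
  out
}

# bootstrap resampling weight matrix: B rows of multinomial counts / n
resample_weights <- function(n, B, seed = NULL) {
  with_seed(seed, {
    W <- matrix(0, B, n)
    for (b in seq_len(B))
      W[b, ] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    W / n
  })
}

# t-percentile bootstrap for the ERDS value 100 * (mean(A) - mean(r)) /
# mean(r), columnwise over X (trials x time), with per-trial reference
# power r.  Studentization uses the delta-method standard error of the
# ratio, recomputed inside every resample.  The significance decision
# uses the empirical tails of the studentized resamples directly (the
# (1 - alpha) interval excludes 0 iff the pivot est/se0 falls outside the
# central resample mass); explicit interval endpoints are interpolated
# type-7 quantiles, computed only on request.
tperc_bootstrap <- function(X, r, W, alpha, want_interval = FALSE) {
  n <- nrow(X); B <- nrow(W)
  ratio_se <- function(ma, mr, va, vr, cab) {
    v <- va / n + (ma / mr)^2 * vr / n - 2 * (ma / mr) * cab / n
    (100 / mr) * sqrt(pmax(v, 0))
  }
  ub <- n / (n - 1)
  a0 <- colMeans(X); r0 <- mean(r)
  if (r0 == 0) stopf("reference power is zero (degenerate input)")
  va0 <- (colMeans(X^2) - a0^2) * ub
  vr0 <- (mean(r^2) - r0^2) * ub
  cab0 <- (colMeans(X * r) - a0 * r0) * ub
  est <- 100 * (a0 / r0 - 1)
  se0 <- ratio_se(a0, r0, va0, vr0, cab0)

  m1 <- W %*% X
  m2 <- W %*% X^2
  r1 <- as.vector(W %*% r)
  r2 <- as.vector(W %*% r^2)
  xr <- W %*% (X * r)
  va <- (m2 - m1^2) * ub
  vr <- (r2 - r1^2) * ub
  cab <- (xr - m1 * r1) * ub
  theta <- 100 * (m1 / r1 - 1)
  se <- ratio_se(m1, r1, va, vr, cab)
  tstat <- (theta - matrix(est, B, length(est), byrow = TRUE)) / se
  tstat[se == 0] <- 0

  nt <- length(est)
  pivot <- ifelse(se0 > 0, est / se0, 0)
  piv_m <- matrix(pivot, B, nt, byrow = TRUE)
  f_le <- colMeans(tstat <= piv_m)   # CI lies above 0 iff f strictly > 1-a/2
  f_lt <- colMeans(tstat < piv_m)    # CI lies below 0 iff f < a/2
  mask <- ifelse(se0 > 0,
                 f_le > 1 - alpha / 2 | f_lt < alpha / 2,
                 est != 0)
  out <- list(estimate = est, mask = mask)
  if (want_interval) {
    q <- col_quantiles(tstat, c(alpha / 2, 1 - alpha / 2))
    out$lower <- est - q[2, ] * se0
    out$upper <- est - q[1, ] * se0
  }
  out
}

#' t-percentile bootstrap significance of ERDS values
#'
#' Resamples trials with replacement `B` times and builds a studentized
#' (t-percentile) bootstrap interval for the mean ERDS value at each time
#' point; a point is significant iff the (1 - alpha) interval excludes
#' zero.  Deterministic under a fixed seed.
#'
#' @param power trials x time matrix of band power for one channel/band.
#' @param reference per-trial reference power (mean over the reference
#'   window), length `nrow(power)`.
#' @param alpha significance level (default 0.05).
#' @param B number of bootstrap resamples (>= 200; default 1000).
#' @param seed RNG seed for the resampling.
#' @return List with `estimate` (ERDS %), `lower`, `upper` (interval) and
#'   logical `mask`.
#' @export
bootstrap_significance <- function(power, reference, alpha = 0.05,
                                   B = 1000, seed = NULL) {
  if (B < 200) stopf("B must be >= 200")
  if (nrow(power) < 5) stopf("need >= 5 trials for the bootstrap")
  W <- resample_weights(nrow(power), B, seed)
  tperc_bootstrap(power, reference, W, alpha, want_interval = TRUE)
}

#' ERD/ERS time-frequency map with bootstrap significance
#'
#' For every (channel, band, time) pixel computes the percentage power
#' change relative to the pre-cue reference interval,
#' `ERDS% = (A - R) / R * 100`, where `A` is the trial-averaged band power
#' at that pixel and `R` the trial-averaged band power in the reference
#' window.  Negative values (>= -100 by construction) are ERD, positive
#' ERS.  Pixel-wise significance is assessed with the t-percentile
#' bootstrap at level `alpha`; the same trial resamples are used for all
#' pixels.  Pixels within `edge_exclude_s` of the trial edges are masked
#' `NA` (filter settling transients, not ERD).  No multiple-comparison
#' correction is applied across pixels (maps mark pixel-wise
#' significance).
#'
#' @param epochs an `epoch_set` (>= 5 unrejected trials).
#' @param grid a [band_grid()].
#' @param reference_window reference interval in seconds relative to trial
#'   start (default: the epoch set's own).
#' @param channels channel subset to map (default all).
#' @param smooth_s power smoothing window, seconds.
#' @param t_step time resolution of the map, seconds (power is read every
#'   `t_step`).
#' @param alpha significance level.
#' @param B bootstrap resamples.
#' @param seed RNG seed (mandatory for reproducible masks).
#' @param edge_exclude_s trial-edge exclusion zone, seconds.
#' @return An `erds_map`: list with `values` and `mask` arrays (channels x
#'   bands x times), `times`, `grid`, `channels`, plus the settings used.
#' @export
compute_erds_map <- function(epochs, grid = band_grid(),
                             reference_window = epochs$reference_window,
                             channels = epochs$labels,
                             smooth_s = 0.25, t_step = 1 / 16,
                             alpha = 0.05, B = 1000, seed = 1,
                             edge_exclude_s = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (sum(!epochs$rejected) < 5) stopf("need >= 5 unrejected trials")
  epochs <- select_channels(epochs, channels)
  fs <- epochs$fs
  d3 <- dim(epochs$data)[3]
  keep_t <- seq(1, d3, by = max(1L, round(t_step * fs)))
  times <- (keep_t - 1) / fs + epochs$window[1]
  ref_idx <- which(times >= reference_window[1] & times < reference_window[2])
  if (!length(ref_idx)) stopf("reference window contains no map time points")
  n_ok <- sum(!epochs$rejected)
  W <- resample_weights(n_ok, B, seed)
  nb <- nrow(grid)
  vals <- array(NA_real_, c(length(channels), nb, length(times)),
                dimnames = list(channels, NULL, NULL))
  mask <- array(NA, c(length(channels), nb, length(times)),
                dimnames = list(channels, NULL, NULL))
  valid_t <- times >= (epochs$window[1] + edge_exclude_s) &
    times <= (epochs$window[2] - edge_exclude_s)
  for (b in seq_len(nb)) {
    pw <- band_power_trials(epochs, c(grid$low[b], grid$high[b]),
                            smooth_s = smooth_s)
    for (c in seq_along(channels)) {
      X <- pw[, c, keep_t, drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, nrow = dim(pw)[1])
      r <- rowMeans(X[, ref_idx, drop = FALSE])
      bs <- tperc_bootstrap(X, r, W, alpha)
      vals[c, b, ] <- bs$estimate
      mask[c, b, ] <- ifelse(valid_t, bs$mask, NA)
    }
  }
  structure(list(values = vals, mask = mask, times = times, grid = grid,
                 channels = channels, alpha = alpha, B = B, seed = seed,
                 reference_window = reference_window,
                 cue_onset = epochs$cue_onset, n_trials = n_ok),
            class = "erds_map")
}

#' @export
print.erds_map <- function(x, ...) {
  frac <- mean(x$mask, na.rm = TRUE)
  cat(sprintf(
    "<erds_map> %d channels x %d bands x %d times, %d trials\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$n_trials))
  cat(sprintf(" ERDS range [%.1f, %.1f]%%; %.1f%% of pixels significant (alpha = %g)\n",
              min(x$values), max(x$values), 100 * frac, x$alpha))
  invisible(x)
}

#' Plot one channel of an ERD/ERS map
#'
#' Time-frequency image of the ERDS percentage (blue = ERS, red = ERD,
#' matching the convention that power decreases are drawn hot); dots mark
#' pixels whose bootstrap interval excludes zero.
#'
#' @param x an `erds_map`.
#' @param channel channel label to plot.
#' @param zlim symmetric colour range, percent.
#' @param ... passed to [graphics::image()].
#' @export
plot.erds_map <- function(x, channel = x$channels[1], zlim = NULL, ...) {
  ci <- match(channel, x$channels)
  if (is.na(ci)) stopf("channel %s not in map", channel)
  z <- t(x$values[ci, , ])
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(z))
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(64)
  graphics::image(x$times, x$grid$center, z, zlim = zlim, col = pal,
                  xlab = "time within trial [s]", ylab = "frequency [Hz]",
                  main = sprintf("ERDS map, %s", channel), ...)
  sig <- which(t(x$mask[ci, , ]) == TRUE, arr.ind = TRUE)
  if (nrow(sig))
    graphics::points(x$times[sig[, 1]], x$grid$center[sig[, 2]], pch = 16,
                     cex = 0.3)
  graphics::abline(v = x$cue_onset, lty = 2)
  invisible(x)
}

#' Fraction of significant pixels in a map
#'
#' Convenience summary used e.g. to check the bootstrap's type-I error on
#' null data; edge-masked pixels are excluded.
#'
#' @param map an `erds_map`.
#' @export
significant_fraction <- function(map) mean(map$mask, na.rm = TRUE)
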