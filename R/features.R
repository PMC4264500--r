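#' Canonical frequency bands for classification
#'
#' The five classical sensorimotor bands: theta 4-7 Hz, alpha 7-13 Hz, and
#' low/mid/high beta 13-19, 19-25, 25-30 Hz.
#'
#' @return A data.frame with columns `band`, `low`, `high`.
#' @export
canonical_bands <- function() {
  data.frame(band = c("theta", "alpha", "beta_low", "beta_mid", "beta_high"),
             low = c(4, 7, 13, 19, 25),
             high = c(7, 13, 19, 25, 30),
             stringsAsFactors = FALSE)
}

#' Log band-power features on 1-s segments
#'
#' For every trial, channel and band: causal band-pass filter, squaring,
#' and a causal 1-s moving average computed sample by sample; the trial is
#' tiled into consecutive non-overlapping 1-s segments and the smoothed
#' log power is read at each segment's midpoint sample.  A 12-s trial thus
#' yields 12 features per (channel, band), with midpoints at 0.5, 1.5, ...,
#' 11.5 s.  The segment covering the pre-cue reference interval is the
#' reference segment.  Features are causal: the value at a midpoint
#' depends only on samples up to that midpoint.
#'
#' @param epochs an `epoch_set`; rejected trials are excluded.  Trial
#'   length must be an integer number of seconds.
#' @param bands a data.frame like [canonical_bands()].
#' @param power_floor lower clamp applied before the log (guards the
#'   degenerate all-zero signal; clamping is counted and reported via a
#'   warning).
#' @return A `feature_set`: list with `values` (trial x channel x band x
#'   segment array of log power), `midpoints` (s), `ref_segment` (index
#'   into segments), `activity_segments` (post-cue indices), `run`,
#'   `task`, `bands`, `channels`, `trials` (indices into the epoch set).
#' @export
extract_features <- function(epochs, bands = canonical_bands(),
                             power_floor = 1e-12) {
  stopifnot(inherits(epochs, "epoch_set"))
  trial_s <- diff(epochs$window)
  if (abs(trial_s - round(trial_s)) > 1e-9)
    stopf("trial length must be an integer number of seconds")
  n_seg <- as.integer(round(trial_s))
  fs <- epochs$fs
  keep <- which(!epochs$rejected)
  if (!length(keep)) stopf("no unrejected trials")
  midpoints <- epochs$window[1] + seq_len(n_seg) - 0.5
  # midpoint of segment k ([k-1, k) s) is sample (k - 0.5) * fs, 0-based
  mid_idx <- round((midpoints - epochs$window[1]) * fs) + 1L
  ref_segment <- which(midpoints >= epochs$reference_window[1] &
                       midpoints < epochs$reference_window[2])
  if (length(ref_segment) != 1)
    stopf("reference window must cover exactly one 1-s segment")
  activity_segments <- which(midpoints > epochs$cue_onset)
  nch <- length(epochs$labels)
  vals <- array(NA_real_,
                c(length(keep), nch, nrow(bands), n_seg),
                dimnames = list(NULL, epochs$labels, bands$band, NULL))
  n_clamped <- 0L
  for (b in seq_len(nrow(bands))) {
    pw <- band_power_trials(epochs, c(bands$low[b], bands$high[b]),
                            smooth_s = 1, causal = TRUE)
    p <- pw[, , mid_idx, drop = FALSE]
    n_clamped <- n_clamped + sum(p < power_floor)
    vals[, , b, ] <- log(pmax(p, power_floor))
  }
  if (n_clamped > 0)
    warning(sprintf("%d degenerate power values clamped to the floor before log",
                    n_clamped))
  structure(list(values = vals, midpoints = midpoints,
                 ref_segment = ref_segment,
                 activity_segments = activity_segments,
                 run = epochs$run[keep], task = epochs$task[keep],
                 bands = bands, channels = epochs$labels, trials = keep),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_set> %d trials x %d channels x %d bands x %d segments\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf(" reference segment %d (%.1f s), %d activity segments, %d blocks\n",
              x$ref_segment, x$midpoints[x$ref_segment],
              length(x$activity_segments), length(unique(x$run))))
  invisible(x)
}

#' Export a feature set to a tidy table
#'
#' @param x a `feature_set`.
#' @param ... unused.
#' @return data.frame with one row per (trial, channel, band, segment).
#' @export
as.data.frame.feature_set <- function(x, ...) {
  d <- dim(x$values)
  g <- expand.grid(trial = seq_len(d[1]), channel = x$channels,
                   band = x$bands$band, segment = seq_len(d[4]),
                   stringsAsFactors = FALSE)
  g$block <- x$run[g$trial]
  g$midpoint_s <- x$midpoints[g$segment]
  g$value <- as.vector(x$values)
  g
}

# concatenate feature sets from consecutive runs (shared montage/bands);
# run indices are preserved so blocks stay distinct
concat_features <- function(fsets) {
  stopifnot(length(fsets) >= 1)
  f1 <- fsets[[1]]
  if (length(fsets) == 1) return(f1)
  for (f in fsets[-1]) {
    if (!identical(f$channels, f1$channels) ||
        !identical(f$bands, f1$bands) ||
        !identical(f$midpoints, f1$midpoints))
      stopf("feature sets are not compatible")
  }
  vals <- do.call(abind3, lapply(fsets, `[[`, "values"))
  f1$values <- vals
  f1$run <- unlist(lapply(fsets, `[[`, "run"))
  f1$task <- unlist(lapply(fsets, `[[`, "task"))
  f1$trials <- unlist(lapply(fsets, `[[`, "trials"))
  f1
}

# bind 4-d arrays along dimension 1
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n1 <- sum(vapply(arrs, function(a) dim(a)[1], 0))
  out <- array(NA_real_, c(n1, d[2], d[3], d[4]),
               dimnames = c(list(NULL), dimnames(arrs[[1]])[-1]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
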