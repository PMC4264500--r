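#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG signal.  Amplitudes are in
#' microvolts, one row per channel.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel labels (rownames of
#'   `signal` are used when `labels` is missing).
#' @param highpass,lowpass,notch acquisition filter metadata in Hz (`NA` if
#'   unknown or absent).
#' @return An object of class `eeg_recording`: a list with elements
#'   `signal`, `fs`, `labels` and `meta`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 100), 2), fs = 100,
#'                      labels = c("C3", "C4"))
#' n_samples(rec)
#' @export
eeg_recording <- function(signal, fs, labels = rownames(signal),
                          highpass = NA_real_, lowpass = NA_real_,
                          notch = NA_real_) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stopf("`signal` must be a numeric channels x samples matrix")
  if (!is_scalar_num(fs) || fs <= 0) stopf("`fs` must be a positive number")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(signal)))
  labels <- as.character(labels)
  if (length(labels) != nrow(signal))
    stopf("%d labels for %d channels", length(labels), nrow(signal))
  if (anyDuplicated(labels)) stopf("channel labels must be unique")
  rownames(signal) <- labels
  structure(list(signal = signal, fs = fs, labels = labels,
                 meta = list(highpass = highpass, lowpass = lowpass,
                             notch = notch)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat(" channels:", paste(utils::head(x$labels, 8), collapse = " "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname eeg_recording
#' @param x an `eeg_recording`.
#' @export
n_samples <- function(x) ncol(x$signal)

#' Cue event list
#'
#' Events mark trial starts (the beep at t = 0 of each trial); the verbal
#' cue follows at a fixed latency within the trial.  Sample indices are
#' 0-based so that `onset_sample = onset_s * fs` exactly.
#'
#' @param onset_sample integer vector of 0-based trial-start samples,
#'   strictly increasing.
#' @param fs sampling rate the onsets refer to, Hz.
#' @param label character vector of task labels (recycled if length 1).
#' @param run integer run (block) index per event, non-decreasing.
#' @return A `data.frame` of class `event_list` with columns
#'   `onset_sample`, `onset_s`, `label`, `run`.
#' @export
event_list <- function(onset_sample, fs, label, run) {
  onset_sample <- as.integer(onset_sample)
  if (any(diff(onset_sample) <= 0)) stopf("event onsets must be strictly increasing")
  if (any(onset_sample < 0)) stopf("onset samples are 0-based and non-negative")
  n <- length(onset_sample)
  label <- rep_len(as.character(label), n)
  run <- as.integer(rep_len(run, n))
  if (is.unsorted(run)) stopf("run indices must be non-decreasing")
  structure(data.frame(onset_sample = onset_sample,
                       onset_s = onset_sample / fs,
                       label = label, run = run,
                       stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

#' Cut a continuous recording into fixed-length trials
#'
#' Pure slicing: trial t, channel c, sample s equals the recording at
#' `onset(t) + s`.  No filtering or baseline correction is applied.
#' Windows are half-open `[start, stop)` in samples so a 12-s window at
#' 512 Hz yields exactly 6144 samples.
#'
#' @param recording an [eeg_recording()].
#' @param events an [event_list()].
#' @param window numeric length-2, trial window in seconds relative to the
#'   event onset (default `c(0, 12)`).
#' @param cue_onset cue latency within the trial, seconds.
#' @param reference_window pre-cue reference interval within the trial,
#'   seconds; must precede `cue_onset`.
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array), `fs`, `labels`, `task`, `run`, `rejected`, `window`,
#'   `cue_onset`, `reference_window`.
#' @export
epoch <- function(recording, events, window = c(0, 12), cue_onset = 2,
                  reference_window = c(1, 2)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(window) != 2 || diff(window) <= 0) stopf("bad trial window")
  if (reference_window[2] > cue_onset)
    stopf("reference window must end at or before the cue onset")
  fs <- recording$fs
  n_win <- round(diff(window) * fs)
  n_trials <- nrow(events)
  n_chan <- nrow(recording$signal)
  dat <- array(NA_real_, c(n_trials, n_chan, n_win),
               dimnames = list(NULL, recording$labels, NULL))
  if (n_trials > 0) {
    start0 <- events$onset_sample + round(window[1] * fs)  # 0-based
    for (t in seq_len(n_trials)) {
      idx <- start0[t] + seq_len(n_win)   # 1-based slice of [start, stop)
      if (start0[t] < 0 || max(idx) > n_samples(recording))
        stopf("trial %d (onset sample %d) extends outside the recording",
              t, events$onset_sample[t])
      dat[t, , ] <- recording$signal[, idx, drop = FALSE]
    }
  }
  structure(list(data = dat, fs = fs, labels = recording$labels,
                 task = if (n_trials) events$label else character(0),
                 run = if (n_trials) events$run else integer(0),
                 rejected = logical(n_trials),
                 window = window, cue_onset = cue_onset,
                 reference_window = reference_window),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz (%d rejected)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, sum(x$rejected)))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `epoch_set`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Rescale an event list to a downsampled recording
#'
#' Maps 0-based onsets recorded at the acquisition rate onto the sample
#' grid of a recording decimated by `factor`.
#'
#' @param events an [event_list()].
#' @param factor decimation factor used in [downsample()].
#' @param fs original sampling rate, Hz.
#' @return An [event_list()] at `fs / factor`.
#' @export
resample_events <- function(events, factor, fs) {
  event_list(round(events$onset_sample / factor), fs = fs / factor,
             label = events$label, run = events$run)
}

#' Subset the channels of a recording or epoch set
#'
#' @param x an `eeg_recording` or `epoch_set`.
#' @param channels character vector of labels to keep.
#' @return Object of the same class restricted to `channels`.
#' @export
select_channels <- function(x, channels) {
  miss <- setdiff(channels, x$labels)
  if (length(miss)) stopf("unknown channels: %s", paste(miss, collapse = ", "))
  if (inherits(x, "eeg_recording")) {
    x$signal <- x$signal[channels, , drop = FALSE]
  } else if (inherits(x, "epoch_set")) {
    x$data <- x$data[, channels, , drop = FALSE]
  } else stopf("unsupported class")
  x$labels <- channels
  x
}

#' Downsample a recording or epoch set
#'
#' Low-pass filters at 80% of the new Nyquist frequency and keeps every
#' `factor`-th sample.  The default zero-phase filtering suits offline
#' analysis; `causal = TRUE` uses a forward-only Butterworth filter as a
#' physically realizable online chain would.
#'
#' @param x an `eeg_recording` or `epoch_set`.
#' @param factor integer decimation factor (new fs = fs / factor).
#' @param causal use a causal (forward-only) anti-alias filter.
#' @return Same class as `x` at the reduced sampling rate.
#' @export
downsample <- function(x, factor, causal = FALSE) {
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be >= 1")
  if (factor == 1L) return(x)
  bt <- signal::butter(8, 0.8 / factor, "low")
  if (inherits(x, "eeg_recording")) {
    keep <- seq(1, ncol(x$signal), by = factor)
    Y <- filter_mat(bt, t(x$signal), causal = causal)
    x$signal <- t(Y[keep, , drop = FALSE])
    rownames(x$signal) <- x$labels
  } else if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    keep <- seq(1, d[3], by = factor)
    X <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])
    Y <- filter_mat(bt, X, causal = causal)[keep, , drop = FALSE]
    x$data <- aperm(array(Y, c(length(keep), d[1], d[2])), c(2, 3, 1))
    dimnames(x$data) <- list(NULL, x$labels, NULL)
  } else stopf("unsupported class")
  x$fs <- x$fs / factor
  x
}
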