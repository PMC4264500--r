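#' Oscillation specification for the synthetic generator
#'
#' Describes one band-limited cortical rhythm implanted at one channel.
#' The rhythm is narrowband Gaussian noise (not a sinusoid) so that its
#' band-power fluctuates from trial to trial like a real EEG rhythm.
#' During the per-trial modulation window its amplitude is scaled by
#' `activity_amplitude_factor`: a factor < 1 implants an ERD (power drops
#' to factor^2), a factor > 1 an ERS.
#'
#' @param channel channel label carrying the rhythm.
#' @param center_freq centre frequency, Hz.
#' @param bandwidth full width at half maximum of the spectral peak, Hz.
#' @param baseline_amplitude RMS amplitude outside the modulation window,
#'   microvolts.
#' @param activity_amplitude_factor amplitude scaling during the
#'   modulation window (> 0).
#' @param modulation_onset,modulation_duration modulation window within
#'   each trial, seconds from trial start.
#' @return A list of class `oscillation_spec`.
#' @export
oscillation_spec <- function(channel, center_freq, bandwidth = 2,
                             baseline_amplitude = 8,
                             activity_amplitude_factor = 0.5,
                             modulation_onset = 2,
                             modulation_duration = 10) {
  if (activity_amplitude_factor <= 0)
    stopf("activity_amplitude_factor must be > 0")
  structure(list(channel = channel, center_freq = center_freq,
                 bandwidth = bandwidth,
                 baseline_amplitude = baseline_amplitude,
                 activity_amplitude_factor = activity_amplitude_factor,
                 modulation_onset = modulation_onset,
                 modulation_duration = modulation_duration),
            class = "oscillation_spec")
}

#' Artifact specification for the synthetic generator
#'
#' One transient, high-amplitude artifact: a Hann-windowed burst of
#' band-limited (2-40 Hz) noise, additive on one channel of one trial and
#' scaled so that its peak equals `amplitude_factor` times the channel's
#' RMS amplitude — emulating muscle/movement transients.
#'
#' @param trial 1-based trial index.
#' @param channel channel label.
#' @param onset onset within the trial, seconds.
#' @param duration burst duration, seconds.
#' @param amplitude_factor peak amplitude in units of channel RMS.
#' @export
artifact_spec <- function(trial, channel, onset, duration = 0.3,
                          amplitude_factor = 10) {
  structure(list(trial = as.integer(trial), channel = channel,
                 onset = onset, duration = duration,
                 amplitude_factor = amplitude_factor),
            class = "artifact_spec")
}

#' Configuration of a synthetic cue-based EEG session
#'
#' Defaults reproduce the cue-based command-following paradigm: 12-s
#' trials (beep at t = 0, verbal cue at t = 2 s, reference interval
#' second 1-2), three runs of 15 trials (45 trials/task) separated by
#' random 4-6 s pauses, recorded from 32 channels at 512 Hz.  The default
#' signal model implants a focal 10-Hz (alpha/mu) rhythm at Cz of 8 uV RMS
#' — a prominent central rhythm, roughly 13 dB above the 1/f background in
#' its band — whose amplitude halves during the post-cue imagery period
#' (a -75% ERD), on a 1/f background of 5 uV RMS per channel.
#'
#' @param channel_labels montage labels; default the 32-channel
#'   [channel_grid()] montage.
#' @param fs sampling rate, Hz.
#' @param trial_length trial duration, seconds.
#' @param cue_onset cue latency within the trial, seconds.
#' @param reference_window pre-cue reference interval, seconds (must lie
#'   before `cue_onset` and within the trial).
#' @param n_trials_per_run,n_runs block structure (runs are the CV blocks).
#' @param pause_range inter-trial pause bounds, seconds.
#' @param task_label task announced by the cue (one task per session).
#' @param oscillation_specs list of [oscillation_spec()]s.
#' @param noise_exponent spectral slope of the 1/f^a background.
#' @param noise_scale background RMS amplitude per channel, microvolts.
#' @param artifact_specs list of [artifact_spec()]s.
#' @param seed integer RNG seed; identical config + seed gives
#'   bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(channel_labels = channel_grid()$label,
                              fs = 512, trial_length = 12, cue_onset = 2,
                              reference_window = c(1, 2),
                              n_trials_per_run = 15, n_runs = 3,
                              pause_range = c(4, 6),
                              task_label = "sport",
                              oscillation_specs = list(
                                oscillation_spec("Cz", 10)),
                              noise_exponent = 1, noise_scale = 5,
                              artifact_specs = list(), seed = 1) {
  cfg <- structure(list(
    channel_labels = as.character(channel_labels), fs = fs,
    trial_length = trial_length, cue_onset = cue_onset,
    reference_window = reference_window,
    n_trials_per_run = as.integer(n_trials_per_run),
    n_runs = as.integer(n_runs), pause_range = pause_range,
    task_label = task_label, oscillation_specs = oscillation_specs,
    noise_exponent = noise_exponent, noise_scale = noise_scale,
    artifact_specs = artifact_specs, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (anyDuplicated(cfg$channel_labels)) stopf("duplicate channel labels")
  if (cfg$fs <= 0) stopf("fs must be positive")
  rw <- cfg$reference_window
  if (length(rw) != 2 || rw[1] >= rw[2]) stopf("bad reference window")
  if (rw[1] < 0 || rw[2] > cfg$cue_onset || cfg$cue_onset >= cfg$trial_length)
    stopf("reference window must lie before the cue and inside the trial")
  if (cfg$pause_range[1] < 0 || diff(cfg$pause_range) < 0)
    stopf("bad pause range")
  for (os in cfg$oscillation_specs) {
    if (!os$channel %in% cfg$channel_labels)
      stopf("oscillation channel %s not in montage", os$channel)
    if (os$modulation_onset < 0 ||
        os$modulation_onset + os$modulation_duration > cfg$trial_length)
      stopf("modulation window exceeds the trial for channel %s", os$channel)
  }
  # reject overlapping rhythms on the same channel (ground truth would be
  # ambiguous there)
  specs <- cfg$oscillation_specs
  if (length(specs) > 1) {
    for (i in seq_along(specs)) for (j in seq_along(specs)) {
      if (i >= j) next
      a <- specs[[i]]; b <- specs[[j]]
      if (a$channel == b$channel &&
          abs(a$center_freq - b$center_freq) < (a$bandwidth + b$bandwidth) / 2)
        stopf("overlapping oscillation specs on channel %s", a$channel)
    }
  }
  for (as_ in cfg$artifact_specs) {
    if (!as_$channel %in% cfg$channel_labels)
      stopf("artifact channel %s not in montage", as_$channel)
    if (as_$onset < 0 || as_$onset + as_$duration > cfg$trial_length)
      stopf("artifact span outside trial %d", as_$trial)
    if (as_$trial < 1 || as_$trial > cfg$n_trials_per_run * cfg$n_runs)
      stopf("artifact trial index %d out of range", as_$trial)
  }
  invisible(cfg)
}

# Gaussian noise spectrally shaped in the frequency domain: white noise is
# transformed, multiplied by |H(f)| and transformed back, which gives exact
# spectral control.  `amp_fun` maps frequency (Hz, >= 0) to amplitude.
shaped_noise <- function(n, fs, amp_fun) {
  m <- stats::nextn(n)            # pad to a fast FFT length, then trim
  x <- stats::rnorm(m)
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * fs / m
  H <- amp_fun(f)
  H[1] <- 0   # remove DC
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / m
  y[seq_len(n)]
}

# 1/f^a background, scaled to an exact RMS.  The spectrum is flattened
# below 0.5 Hz, mimicking the acquisition high-pass.
pink_noise <- function(n, fs, exponent, scale) {
  y <- shaped_noise(n, fs, function(f) pmax(f, 0.5)^(-exponent / 2))
  y / rms(y) * scale
}

# unit-RMS narrowband Gaussian rhythm: Gaussian spectral bump with the
# given FWHM bandwidth
narrowband_rhythm <- function(n, fs, f0, bw) {
  sigma <- bw / (2 * sqrt(2 * log(2)))
  y <- shaped_noise(n, fs, function(f) exp(-(f - f0)^2 / (2 * sigma^2)))
  y / rms(y)
}

# amplitude envelope for one oscillation spec over the whole recording:
# 1 at baseline, `factor` inside each trial's modulation window, with
# raised-cosine ramps to avoid spectral splatter
modulation_envelope <- function(n_total, fs, trial_starts0, os,
                                ramp_s = 0.25) {
  env <- rep(1, n_total)
  f <- os$activity_amplitude_factor
  if (f == 1) return(env)
  nr <- max(1L, round(ramp_s * fs))
  ramp_up <- (1 - cos(pi * seq_len(nr) / nr)) / 2      # 0 -> 1
  for (s0 in trial_starts0) {
    a <- s0 + round(os$modulation_onset * fs) + 1L      # 1-based
    b <- s0 + round((os$modulation_onset + os$modulation_duration) * fs)
    b <- min(b, n_total)
    if (a > n_total) next
    env[a:b] <- f
    on_idx <- a:min(a + nr - 1L, n_total)
    env[on_idx] <- 1 + (f - 1) * ramp_up[seq_along(on_idx)]
    off_idx <- (b + 1L):min(b + nr, n_total)
    if (b < n_total)
      env[off_idx] <- f + (1 - f) * ramp_up[seq_along(off_idx)]
  }
  env
}

#' Generate a synthetic cue-based EEG session
#'
#' Produces a continuous multichannel recording laid out as
#' trial-pause-trial-... (one random pause after every trial), the cue
#' event list, and the ground truth a test can score against: the per-trial
#' task labels, the implanted ERD/ERS percentage per (channel, band) —
#' `(factor^2 - 1) * 100` for an amplitude-scaled rhythm — and the exact
#' sample spans of injected artifacts.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `recording` ([eeg_recording()]), `events`
#'   ([event_list()]) and `truth` (class `ground_truth`).
#' @examples
#' cfg <- simulation_config(channel_labels = c("C1", "Cz", "C2"),
#'                          fs = 128, n_runs = 1, n_trials_per_run = 3,
#'                          oscillation_specs = list(oscillation_spec("Cz", 10)))
#' ses <- generate_session(cfg)
#' ses$recording
#' @export
generate_session <- function(config) {
  validate_sim_config(config)
  fs <- config$fs
  n_trials <- config$n_trials_per_run * config$n_runs
  len_trial <- round(config$trial_length * fs)
  with_seed(config$seed, {
    pauses <- stats::runif(n_trials, config$pause_range[1],
                           config$pause_range[2])
    len_pause <- round(pauses * fs)
    starts0 <- cumsum(c(0L, (len_trial + len_pause)[-n_trials]))  # 0-based
    n_total <- sum(len_trial + len_pause)

    sig <- matrix(0, length(config$channel_labels), n_total,
                  dimnames = list(config$channel_labels, NULL))
    for (c in seq_len(nrow(sig)))
      sig[c, ] <- pink_noise(n_total, fs, config$noise_exponent,
                             config$noise_scale)
    for (os in config$oscillation_specs) {
      rhythm <- narrowband_rhythm(n_total, fs, os$center_freq, os$bandwidth) *
        os$baseline_amplitude
      env <- modulation_envelope(n_total, fs, starts0, os)
      sig[os$channel, ] <- sig[os$channel, ] + rhythm * env
    }
    rec <- eeg_recording(sig, fs = fs, labels = config$channel_labels,
                         highpass = 0.5, lowpass = 100, notch = 50)
    events <- event_list(starts0, fs = fs, label = config$task_label,
                         run = rep(seq_len(config$n_runs),
                                   each = config$n_trials_per_run))
    inj <- inject_artifacts(rec, events, config$artifact_specs)
    truth <- structure(list(
      task = events$label,
      erds = do.call(rbind, c(list(
        data.frame(channel = character(0), center_freq = numeric(0),
                   band_low = numeric(0), band_high = numeric(0),
                   implanted_pct = numeric(0))),
        lapply(config$oscillation_specs, function(os) data.frame(
          channel = os$channel, center_freq = os$center_freq,
          band_low = os$center_freq - os$bandwidth / 2,
          band_high = os$center_freq + os$bandwidth / 2,
          implanted_pct = (os$activity_amplitude_factor^2 - 1) * 100)))),
      artifacts = inj$annotations), class = "ground_truth")
    list(recording = inj$recording, events = events, truth = truth)
  })
}

#' Generate a resting-state segment
#'
#' Artifact-free, modulation-free signal from the same montage, sampling
#' rate and signal model as [generate_session()] (background plus baseline
#' rhythms), for calibrating the autoregressive artifact detector.
#'
#' @param config a [simulation_config()].
#' @param duration segment length in seconds (>= 10).
#' @return An [eeg_recording()]; no events are produced.
#' @export
generate_resting <- function(config, duration = 60) {
  validate_sim_config(config)
  if (!is_scalar_num(duration) || duration < 10)
    stopf("resting duration must be >= 10 s")
  fs <- config$fs
  n <- round(duration * fs)
  with_seed(config$seed + 1L, {
    sig <- matrix(0, length(config$channel_labels), n,
                  dimnames = list(config$channel_labels, NULL))
    for (c in seq_len(nrow(sig)))
      sig[c, ] <- pink_noise(n, fs, config$noise_exponent, config$noise_scale)
    for (os in config$oscillation_specs)
      sig[os$channel, ] <- sig[os$channel, ] +
        narrowband_rhythm(n, fs, os$center_freq, os$bandwidth) *
        os$baseline_amplitude
    eeg_recording(sig, fs = fs, labels = config$channel_labels,
                  highpass = 0.5, lowpass = 100, notch = 50)
  })
}

empty_artifact_annotations <- function() {
  data.frame(trial = integer(0), channel = character(0),
             start_sample = integer(0), end_sample = integer(0),
             amplitude_factor = numeric(0), stringsAsFactors = FALSE)
}

#' Inject transient artifacts into a recording
#'
#' Adds Hann-windowed bursts of 2-40 Hz noise at the specified trial
#' positions, each scaled so its peak equals `amplitude_factor` times the
#' channel's pre-injection RMS.  Returns the modified recording together
#' with sample-exact annotations (0-based, half-open spans) for use as a
#' detection oracle.
#'
#' @param recording an [eeg_recording()].
#' @param events the session's [event_list()] (maps trial index to
#'   samples).
#' @param artifact_specs list of [artifact_spec()]s.
#' @return List with `recording` and `annotations` (data.frame: trial,
#'   channel, start_sample, end_sample, amplitude_factor).
#' @export
inject_artifacts <- function(recording, events, artifact_specs) {
  ann <- empty_artifact_annotations()
  if (!length(artifact_specs))
    return(list(recording = recording, annotations = ann))
  fs <- recording$fs
  bt <- signal::butter(4, pmin(c(2, 40), fs / 2 * 0.95) / (fs / 2), "pass")
  for (as_ in artifact_specs) {
    if (as_$trial > nrow(events)) stopf("artifact trial %d has no event", as_$trial)
    s0 <- events$onset_sample[as_$trial] + round(as_$onset * fs)  # 0-based
    nb <- max(4L, round(as_$duration * fs))
    if (s0 < 0 || s0 + nb > n_samples(recording))
      stopf("artifact span outside the recording (trial %d)", as_$trial)
    ch_rms <- rms(recording$signal[as_$channel, ])
    burst <- signal::filtfilt(bt, stats::rnorm(nb))
    burst <- burst * signal::hanning(nb)
    burst <- burst / max(abs(burst)) * as_$amplitude_factor * ch_rms
    idx <- s0 + seq_len(nb)
    recording$signal[as_$channel, idx] <-
      recording$signal[as_$channel, idx] + burst
    ann <- rbind(ann, data.frame(trial = as_$trial, channel = as_$channel,
                                 start_sample = s0, end_sample = s0 + nb,
                                 amplitude_factor = as_$amplitude_factor,
                                 stringsAsFactors = FALSE))
  }
  list(recording = recording, annotations = ann)
}
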