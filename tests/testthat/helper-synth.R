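# shared fixtures: small montages and sessions generated in code

# 5-channel central montage at the 128 Hz analysis rate; defaults otherwise
# follow the full paradigm (12-s trials, cue at 2 s, reference 1-2 s)
cfg_small <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(channel_labels = c("C1", "Cz", "C2", "FCz", "CPz"),
                   fs = 128, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# generate + epoch in one go (fs kept as configured)
small_epochs <- function(cfg, window = c(0, cfg$trial_length)) {
  ses <- generate_session(cfg)
  list(session = ses,
       epochs = epoch(ses$recording, ses$events, window = window,
                      cue_onset = cfg$cue_onset,
                      reference_window = cfg$reference_window))
}

# hand-built feature set: Gaussian features, with the activity segments of
# `shift_channel`/`shift_band` shifted by `delta` (log-power units)
synth_features <- function(n_trials = 30, n_runs = 3, delta = 0, sd = 1,
                           seed = 1, channels = c("C1", "Cz"),
                           shift_channel = "Cz", shift_band = "alpha") {
  bands <- canonical_bands()
  n_seg <- 12
  vals <- imagerybci:::with_seed(seed,
    array(stats::rnorm(n_trials * length(channels) * nrow(bands) * n_seg,
                       sd = sd),
          c(n_trials, length(channels), nrow(bands), n_seg),
          dimnames = list(NULL, channels, bands$band, NULL)))
  act <- 3:12
  vals[, shift_channel, shift_band, act] <-
    vals[, shift_channel, shift_band, act] + delta
  structure(list(values = vals, midpoints = seq_len(n_seg) - 0.5,
                 ref_segment = 2L, activity_segments = act,
                 run = sort(rep_len(seq_len(n_runs), n_trials)),
                 task = rep("sport", n_trials), bands = bands,
                 channels = channels, trials = seq_len(n_trials)),
            class = "feature_set")
}

# log-log periodogram slope of a signal (independent check of the 1/f
# background): least-squares fit over [f_lo, f_hi]
periodogram_slope <- function(x, fs, f_lo = 2, f_hi = 40) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = FALSE)
  sel <- sp$freq >= f_lo & sp$freq <= f_hi
  unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
}
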