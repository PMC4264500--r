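#' Feedback rule for the online paradigm
#'
#' Positive ("biased") feedback: the confirmation message is delivered
#' only when the classifier predicted the imagery class for strictly more
#' than `threshold` of the imagery period, and the trial passed the
#' artifact detector; otherwise — including every artifact-flagged trial —
#' the neutral pause message is delivered.
#'
#' @param threshold correct-prediction fraction that must be exceeded
#'   (strictly) for positive feedback; default 0.5.
#' @param correct_msg,pause_msg delivered message strings.
#' @return A `feedback_rule` list.
#' @export
feedback_rule <- function(threshold = 0.5,
                          correct_msg = "correct",
                          pause_msg = "pause") {
  if (threshold < 0 || threshold >= 1) stopf("threshold must be in [0, 1)")
  structure(list(threshold = threshold, correct_msg = correct_msg,
                 pause_msg = pause_msg), class = "feedback_rule")
}

#' Apply the feedback rule to one trial
#'
#' @param rule a [feedback_rule()].
#' @param fraction correct-prediction fraction over the imagery period.
#' @param artifact was the trial artifact-flagged?
#' @return The delivered message string.
#' @export
apply_feedback_rule <- function(rule, fraction, artifact) {
  if (isTRUE(artifact) || !(fraction > rule$threshold)) rule$pause_msg
  else rule$correct_msg
}

#' Simulate an online feedback run
#'
#' Replays a recorded (or synthetic) run through the causal online chain:
#' per trial, the selected Laplacian channel is causally band-pass
#' filtered, squared and averaged over a trailing 1-s window, the log
#' power is classified sample by sample with the fixed LDA model over the
#' imagery period, and feedback is assigned by the rule.  The AR artifact
#' detector runs concurrently on the trial and overrides the feedback to
#' the pause message.  Everything is causal: the decision for trial t
#' uses no samples after trial t's end and no later trials.
#'
#' @param recording continuous [eeg_recording()] of the run.
#' @param events the run's [event_list()].
#' @param model a fixed `lda_model` trained on (reference vs. activity)
#'   log band-power features of the selected channel/band.
#' @param selected list with `channel` (Laplacian centre label) and
#'   `band` (name from the feature band table, or numeric edges).
#' @param armodel `ar_model` for artifact gating (same sampling rate).
#' @param montage the [laplacian_montage()].
#' @param rule a [feedback_rule()].
#' @param window,cue_onset,reference_window trial timing, seconds.
#' @param imagery_window span over which predictions are counted; default
#'   cue onset to trial end.
#' @param bands band table resolving a named `selected$band`.
#' @return A data.frame of trial outcomes: `trial`, `fraction` (the true
#'   per-trial correct-prediction fraction, kept even when feedback is
#'   withheld so the feedback bias stays quantifiable), `artifact`,
#'   `feedback`.
#' @export
simulate_online_run <- function(recording, events, model, selected,
                                armodel, montage, rule = feedback_rule(),
                                window = c(0, 12), cue_onset = 2,
                                reference_window = c(1, 2),
                                imagery_window = NULL,
                                bands = canonical_bands()) {
  stopifnot(inherits(model, "lda_model"), inherits(armodel, "ar_model"))
  if (!isTRUE(all.equal(recording$fs, armodel$fs)))
    stopf("sampling rate mismatch between recording and artifact model")
  band <- selected$band
  if (is.character(band)) {
    row <- match(band, bands$band)
    if (is.na(row)) stopf("unknown band: %s", band)
    band <- c(bands$low[row], bands$high[row])
  }
  epochs <- epoch(recording, events, window = window, cue_onset = cue_onset,
                  reference_window = reference_window)
  epochs <- detect_artifact_trials(epochs, armodel, montage)
  artifact_flags <- epochs$rejected
  der <- laplacian_derive(epochs, montage)
  if (!selected$channel %in% der$labels)
    stopf("selected channel %s is not derivable", selected$channel)
  if (is.null(imagery_window)) imagery_window <- c(cue_onset, window[2])
  fs <- der$fs
  t_axis <- window[1] + (seq_len(dim(der$data)[3]) - 1) / fs
  img_idx <- which(t_axis >= imagery_window[1] & t_axis < imagery_window[2])
  bt <- bp_filter(band, fs)
  n_ma <- round(fs)
  out <- data.frame()
  for (t in seq_len(n_trials(epochs))) {
    x <- der$data[t, selected$channel, ]
    p <- causal_ma(as.numeric(signal::filter(bt, x))^2, n_ma)
    feat <- log(pmax(p[img_idx], 1e-12))
    pred <- predict(model, matrix(feat))
    fraction <- mean(pred == 1L)
    out <- rbind(out, data.frame(
      trial = t, fraction = fraction, artifact = artifact_flags[t],
      feedback = apply_feedback_rule(rule, fraction, artifact_flags[t]),
      stringsAsFactors = FALSE))
  }
  out
}

#' Write an online session transcript as JSON lines
#'
#' @param outcomes trial outcome data.frame from [simulate_online_run()].
#' @param path output path (one JSON object per line).
#' @export
write_transcript <- function(outcomes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(outcomes)))
    writeLines(jsonlite::toJSON(as.list(outcomes[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

# train the final 1-D classifier at one selected triple
final_classifier <- function(features, selected) {
  mats <- build_cv_matrices(features)
  idx <- which(mats$meta$channel == selected$channel &
               mats$meta$band == selected$band &
               mats$meta$segment == selected$segment)
  if (length(idx) != 1) stopf("selected triple not found in feature set")
  train_lda(matrix(mats$ref[, mats$cb_of[idx]]), matrix(mats$act[, idx]))
}

#' Recalculate the classifier from recent runs
#'
#' Implements the run-by-run classifier update of the online paradigm:
#' the features of up to the `max_runs` most recent runs are concatenated,
#' the (channel, band, segment) selection and the cross-validated accuracy
#' estimate are recomputed — leave-one-trial-out when only one run is
#' available, nested block-wise otherwise — and the refreshed classifier
#' is trained on all retained data at the selected triple.
#'
#' @param history list of `feature_set`s, one per completed run, oldest
#'   first.
#' @param max_runs how many recent runs to use (default 3).
#' @param seed RNG seed for the CV fold assignments.
#' @param ... passed to the CV routine.
#' @return List with `model` (`lda_model`), `selected` triple and
#'   `result` (`session_result`).
#' @export
recalibrate <- function(history, max_runs = 3, seed = 1, ...) {
  if (!length(history)) stopf("no prior runs to recalibrate from")
  used <- utils::tail(history, max_runs)
  features <- concat_features(used)
  result <- if (length(used) == 1)
    loto_cv(features, seed = seed, ...)
  else
    nested_blockwise_cv(features, seed = seed, ...)
  model <- final_classifier(features, result$selected)
  list(model = model, selected = result$selected, result = result,
       n_runs_used = length(used))
}

#' Decide whether the feedback session continues
#'
#' Deterministic policy over the latest cross-validated estimate:
#' continue with another feedback run iff its significance p-value is at
#' or below the threshold.  Clinical contingencies (fatigue, vigilance)
#' are outside the model; `override` forces a decision and is logged as
#' such.
#'
#' @param result the latest `session_result`.
#' @param p_threshold continue threshold on the exact binomial p-value.
#' @param override optional `"continue"` or `"stop"` forcing the decision
#'   (manual clinical override).
#' @return List with `action` (`"continue"` or `"stop"`) and `reason`.
#' @export
session_controller <- function(result, p_threshold = 0.05,
                               override = NULL) {
  if (!is.null(override)) {
    override <- match.arg(override, c("continue", "stop"))
    return(list(action = override,
                reason = sprintf("manual override: %s", override)))
  }
  if (!inherits(result, "session_result"))
    stopf("no session result available")
  if (result$p_value <= p_threshold)
    list(action = "continue",
         reason = sprintf("accuracy %.0f%% significant (p = %.3g <= %g)",
                          result$accuracy, result$p_value, p_threshold))
  else
    list(action = "stop",
         reason = sprintf("accuracy %.0f%% not significant (p = %.3g > %g)",
                          result$accuracy, result$p_value, p_threshold))
}
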