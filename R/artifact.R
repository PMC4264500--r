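#' Fit the autoregressive inverse filter on resting-state EEG
#'
#' Fits an AR(p) model per monitored Laplacian channel on a resting-state
#' segment (Burg's method by default, which is stable on short segments).
#' The inverse (whitening) filter turns the signal into its one-step
#' prediction error; its RMS on the resting segment defines the artifact
#' detection threshold as exactly 5 x residual RMS per channel.  Transient
#' non-stationarities (muscle or movement artifacts) are poorly predicted
#' by the resting model and throw large prediction errors.
#'
#' @param resting resting-state [eeg_recording()], at least 10 s.
#' @param montage a [laplacian_montage()]; the detector operates on the
#'   Laplacian-derived channels.
#' @param order AR model order (default 10).
#' @param method fitting method passed to [stats::ar()] (default
#'   `"burg"`).
#' @param channels monitored centre channels (default: all derivable).
#' @return An `ar_model`: list with `order`, `fs`, per-channel
#'   `coefficients`, `residual_rms` and `threshold` (= 5 * residual_rms).
#' @export
fit_inverse_filter <- function(resting, montage, order = 10,
                               method = "burg", channels = names(montage)) {
  stopifnot(inherits(resting, "eeg_recording"))
  order <- as.integer(order)
  if (order < 1) stopf("AR order must be >= 1")
  dur <- n_samples(resting) / resting$fs
  if (dur < 10) stopf("resting segment must be >= 10 s (got %.1f s)", dur)
  if (n_samples(resting) < 10 * order)
    stopf("resting segment shorter than 10 x order samples")
  der <- laplacian_derive(resting, montage)
  channels <- intersect(channels, der$labels)
  if (!length(channels)) stopf("no monitored channels derivable")
  coefs <- matrix(0, length(channels), order,
                  dimnames = list(channels, NULL))
  res_rms <- stats::setNames(numeric(length(channels)), channels)
  for (ch in channels) {
    x <- der$signal[ch, ]
    if (!all(is.finite(x))) stopf("non-finite samples on channel %s", ch)
    fit <- stats::ar(x, aic = FALSE, order.max = order, method = method,
                     demean = TRUE)
    coefs[ch, ] <- fit$ar
    e <- whiten(x, fit$ar)
    res_rms[ch] <- rms(e)
  }
  structure(list(order = order, fs = resting$fs, channels = channels,
                 method = method, coefficients = coefs,
                 residual_rms = res_rms, threshold = 5 * res_rms),
            class = "ar_model")
}

# one-step AR prediction error e[t] = x[t] - sum_k a_k x[t-k]; the first
# `order` samples (no full history) are dropped
whiten <- function(x, a) {
  p <- length(a)
  e <- as.numeric(stats::filter(x - mean(x), c(1, -a), method = "convolution",
                                sides = 1))
  e[(p + 1):length(e)]
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> AR(%d), %s, %d channels @ %g Hz\n",
              x$order, x$method, length(x$channels), x$fs))
  cat(sprintf(" residual RMS %.3g-%.3g uV (threshold = 5 x RMS)\n",
              min(x$residual_rms), max(x$residual_rms)))
  invisible(x)
}

#' Detect artifact-contaminated trials
#'
#' Applies the fitted inverse filter to the Laplacian-derived trials and
#' flags a trial as artifactual if on any monitored channel the absolute
#' prediction error exceeds that channel's threshold (5 x resting residual
#' RMS) for at least `min_run` consecutive samples (default 1: a single
#' exceedance discards the trial).  Decisions depend only on the trial's
#' own samples and the fixed resting-state calibration.
#'
#' @param epochs an `epoch_set` (raw channels; the Laplacian derivation is
#'   applied internally).
#' @param model an `ar_model` from [fit_inverse_filter()], fitted at the
#'   same sampling rate.
#' @param montage the [laplacian_montage()] the model was fitted with.
#' @param min_run minimum consecutive exceedance run length.
#' @return The `epoch_set` with the `rejected` flags set and a
#'   `rejection_log` attribute (data.frame: trial, channel,
#'   first_exceedance_sample).
#' @export
detect_artifact_trials <- function(epochs, model, montage, min_run = 1) {
  stopifnot(inherits(model, "ar_model"))
  if (!isTRUE(all.equal(epochs$fs, model$fs)))
    stopf("sampling rate mismatch: epochs %g Hz vs model %g Hz",
          epochs$fs, model$fs)
  nt <- n_trials(epochs)
  log_df <- data.frame(trial = integer(0), channel = character(0),
                       first_exceedance_sample = integer(0),
                       stringsAsFactors = FALSE)
  if (nt == 0) {
    epochs$rejected <- logical(0)
    attr(epochs, "rejection_log") <- log_df
    return(epochs)
  }
  der <- laplacian_derive(epochs, montage)
  flags <- logical(nt)
  for (t in seq_len(nt)) {
    for (ch in model$channels) {
      e <- whiten(der$data[t, ch, ], model$coefficients[ch, ])
      exc <- abs(e) > model$threshold[ch]
      hit <- if (min_run <= 1) any(exc) else {
        r <- rle(exc); any(r$lengths[r$values] >= min_run)
      }
      if (hit) {
        flags[t] <- TRUE
        log_df <- rbind(log_df, data.frame(
          trial = t, channel = ch,
          first_exceedance_sample = model$order + which(exc)[1] - 1L,
          stringsAsFactors = FALSE))
        break
      }
    }
  }
  epochs$rejected <- flags
  attr(epochs, "rejection_log") <- log_df
  epochs
}

#' Serialize an AR artifact model to / from JSON
#' @param model an `ar_model`.
#' @param path JSON file path.
#' @export
write_ar_model <- function(model, path) {
  obj <- unclass(model)
  obj$coefficients <- as.data.frame(t(obj$coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ar_model
#' @export
read_ar_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- t(as.matrix(obj$coefficients))
  rownames(coefs) <- obj$channels
  structure(list(order = obj$order, fs = obj$fs, channels = obj$channels,
                 method = obj$method, coefficients = coefs,
                 residual_rms = stats::setNames(obj$residual_rms, obj$channels),
                 threshold = stats::setNames(obj$threshold, obj$channels)),
            class = "ar_model")
}
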