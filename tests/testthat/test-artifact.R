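# montage whose centre channel keeps the raw signal: neighbours are silent
passthrough_montage <- function() {
  structure(list(Cz = c("C1", "C2")), class = "laplacian_montage")
}

passthrough_recording <- function(x, fs = 128) {
  sig <- rbind(Cz = x, C1 = 0 * x, C2 = 0 * x)
  eeg_recording(sig, fs = fs, labels = c("Cz", "C1", "C2"))
}

test_that("white noise fits as its own innovation", {
  set.seed(10)
  x <- stats::rnorm(128 * 60, sd = 4)
  arm <- fit_inverse_filter(passthrough_recording(x), passthrough_montage(),
                            order = 10)
  expect_lt(max(abs(arm$coefficients["Cz", ])), 0.05)
  expect_equal(unname(arm$residual_rms["Cz"]), 4, tolerance = 0.03)
})

test_that("known AR(2) coefficients are recovered from 60 s of data", {
  phi <- c(0.6, -0.3)
  set.seed(11)
  x <- as.numeric(stats::arima.sim(list(ar = phi), n = 128 * 60))
  arm <- fit_inverse_filter(passthrough_recording(x), passthrough_montage(),
                            order = 2)
  expect_equal(unname(arm$coefficients["Cz", ]), phi, tolerance = 0.05)
})

test_that("the detection threshold is exactly five times the residual RMS", {
  cfg <- cfg_small(seed = 2)
  arm <- fit_inverse_filter(generate_resting(cfg, 60),
                            laplacian_montage(cfg$channel_labels))
  expect_identical(arm$threshold, 5 * arm$residual_rms)
  expect_true(all(arm$residual_rms > 0))
})

test_that("fit preconditions are enforced", {
  mont <- passthrough_montage()
  expect_error(fit_inverse_filter(passthrough_recording(stats::rnorm(128 * 5)),
                                  mont), ">= 10 s")
  expect_error(fit_inverse_filter(passthrough_recording(stats::rnorm(128 * 20)),
                                  mont, order = 0), "order")
  x <- stats::rnorm(128 * 20); x[5] <- NA
  expect_error(fit_inverse_filter(passthrough_recording(x), mont),
               "non-finite")
})

test_that("clean trials pass and spiked trials are flagged", {
  spiked <- seq(2, 30, by = 2)
  specs <- lapply(spiked, function(t) artifact_spec(t, "Cz", onset = 5,
                                                    amplitude_factor = 10))
  cfg <- cfg_small(seed = 13, n_runs = 2, artifact_specs = specs)
  ses <- generate_session(cfg)
  mont <- laplacian_montage(cfg$channel_labels)
  arm <- fit_inverse_filter(generate_resting(cfg, 60), mont)
  ep <- epoch(ses$recording, ses$events)
  ep <- detect_artifact_trials(ep, arm, mont)
  expect_gte(mean(ep$rejected[spiked]), 0.95)
  expect_lte(mean(ep$rejected[-spiked]), 0.10)
  # the rejection log points into flagged trials
  log_df <- attr(ep, "rejection_log")
  expect_true(all(log_df$trial %in% which(ep$rejected)))
})

test_that("detector decisions depend only on the trial's own samples", {
  cfg <- cfg_small(seed = 14, n_runs = 1, n_trials_per_run = 6,
                   artifact_specs = list(artifact_spec(3, "Cz", 5,
                                                       amplitude_factor = 12)))
  ses <- generate_session(cfg)
  mont <- laplacian_montage(cfg$channel_labels)
  arm <- fit_inverse_filter(generate_resting(cfg, 60), mont)
  ep <- epoch(ses$recording, ses$events)
  full <- detect_artifact_trials(ep, arm, mont)$rejected
  # re-detecting on a subset reproduces the same per-trial decisions
  sub <- ep
  sub$data <- ep$data[c(2, 3, 5), , , drop = FALSE]
  sub$task <- ep$task[c(2, 3, 5)]; sub$run <- ep$run[c(2, 3, 5)]
  sub$rejected <- logical(3)
  expect_identical(detect_artifact_trials(sub, arm, mont)$rejected,
                   full[c(2, 3, 5)])
})

test_that("degenerate detector inputs are handled", {
  cfg <- cfg_small(seed = 2)
  mont <- laplacian_montage(cfg$channel_labels)
  arm <- fit_inverse_filter(generate_resting(cfg, 30), mont)
  ses <- generate_session(cfg_small(seed = 2, n_runs = 1, n_trials_per_run = 2))
  ep <- epoch(ses$recording, ses$events)
  # fs mismatch
  bad <- arm; bad$fs <- 512
  expect_error(detect_artifact_trials(ep, bad, mont), "mismatch")
  # empty epoch set -> empty flags
  ev0 <- event_list(integer(0), 128, character(0), integer(0))
  ep0 <- epoch(ses$recording, ev0)
  expect_length(detect_artifact_trials(ep0, arm, mont)$rejected, 0)
})
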