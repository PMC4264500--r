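test_that("identical config and seed give bit-identical sessions", {
  cfg <- cfg_small(seed = 7, n_runs = 1, n_trials_per_run = 3,
                   artifact_specs = list(artifact_spec(2, "C1", 4)))
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  # and a different seed gives different noise
  c <- generate_session(cfg_small(seed = 8, n_runs = 1, n_trials_per_run = 3))
  expect_false(identical(a$recording$signal[1, 1:100],
                         c$recording$signal[1, 1:100]))
})

test_that("session layout follows the paradigm timing", {
  cfg <- cfg_small(seed = 3, n_runs = 2, n_trials_per_run = 4)
  ses <- generate_session(cfg)
  ev <- ses$events
  expect_equal(nrow(ev), 8)
  expect_true(all(diff(ev$onset_sample) > 0))
  # trials never overlap: gaps are trial length plus a 4-6 s pause
  gaps <- diff(ev$onset_sample) / cfg$fs
  expect_true(all(gaps >= cfg$trial_length + cfg$pause_range[1] - 1 / cfg$fs))
  expect_true(all(gaps <= cfg$trial_length + cfg$pause_range[2] + 1 / cfg$fs))
  # total length = sum(trial + pause)
  expect_true(n_samples(ses$recording) >=
                8 * (cfg$trial_length + cfg$pause_range[1]) * cfg$fs)
  expect_equal(ev$run, rep(1:2, each = 4))
  expect_identical(ses$truth$task, ev$label)
})

test_that("implanted ERD ground truth follows factor^2 - 1", {
  cfg <- cfg_small(oscillation_specs = list(
    oscillation_spec("Cz", 10, activity_amplitude_factor = 0.5)))
  ses <- generate_session(cfg)
  expect_equal(ses$truth$erds$implanted_pct, -75)
  cfg2 <- cfg_small(oscillation_specs = list(
    oscillation_spec("Cz", 10, activity_amplitude_factor = sqrt(2))))
  expect_equal(generate_session(cfg2)$truth$erds$implanted_pct, 100)
})

test_that("band power during modulation tracks the squared amplitude factor", {
  # factor 0.5: band power ratio activity/reference -> 0.25 (plus a small
  # 1/f noise floor); factor 1: ratio -> 1
  for (f in c(0.5, 1)) {
    cfg <- cfg_small(seed = 21, n_runs = 1, n_trials_per_run = 15,
                     oscillation_specs = list(
                       oscillation_spec("Cz", 10, activity_amplitude_factor = f)))
    se <- small_epochs(cfg)
    pw <- band_power_trials(se$epochs, c(9, 11))
    t_ax <- (seq_len(dim(pw)[3]) - 1) / cfg$fs
    act <- mean(pw[, "Cz", t_ax >= 3 & t_ax <= 11])
    ref <- mean(pw[, "Cz", t_ax >= 1 & t_ax < 2])
    expect_equal(act / ref, f^2, tolerance = 0.12)
  }
})

test_that("stationarity holds off the modulated channel", {
  cfg <- cfg_small(seed = 4, n_runs = 1, n_trials_per_run = 10)
  se <- small_epochs(cfg)
  pw <- band_power_trials(se$epochs, c(9, 11))
  t_ax <- (seq_len(dim(pw)[3]) - 1) / cfg$fs
  ratio <- mean(pw[, "C1", t_ax >= 3 & t_ax <= 11]) /
    mean(pw[, "C1", t_ax >= 1 & t_ax < 2])
  expect_equal(ratio, 1, tolerance = 0.25)
})

test_that("resting segments have the right length, montage and no modulation", {
  cfg <- simulation_config(channel_labels = c("C1", "Cz"), seed = 2)
  rest <- generate_resting(cfg, duration = 60)
  expect_equal(ncol(rest$signal), 60 * 512)
  expect_identical(rest$labels, c("C1", "Cz"))
  expect_error(generate_resting(cfg, duration = 5), ">= 10")
})

test_that("the 1/f background has the configured spectral slope", {
  cfg <- cfg_small(seed = 6, noise_exponent = 1, oscillation_specs = list())
  rest <- generate_resting(cfg, duration = 120)
  slope <- periodogram_slope(rest$signal["C2", ], cfg$fs)
  expect_equal(slope, -1, tolerance = 0.12)
  cfg2 <- cfg_small(seed = 6, noise_exponent = 2, oscillation_specs = list())
  slope2 <- periodogram_slope(generate_resting(cfg2, 120)$signal["C2", ],
                              cfg2$fs)
  expect_equal(slope2, -2, tolerance = 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(cfg_small(reference_window = c(1.5, 2.5)), "reference window")
  expect_error(cfg_small(oscillation_specs = list(
    oscillation_spec("Cz", 10, modulation_onset = 8,
                     modulation_duration = 10))), "modulation window")
  expect_error(cfg_small(oscillation_specs = list(
    oscillation_spec("Cz", 10), oscillation_spec("Cz", 11))), "overlapping")
  expect_error(oscillation_spec("Cz", 10, activity_amplitude_factor = -1),
               "factor")
  expect_error(cfg_small(artifact_specs = list(
    artifact_spec(1, "Cz", onset = 11.9, duration = 0.5))), "artifact span")
})

test_that("artifact injection is additive, annotated and reversible-free", {
  cfg <- cfg_small(seed = 11, n_runs = 1, n_trials_per_run = 4)
  ses0 <- generate_session(cfg)
  # empty specs leave the recording untouched
  out <- inject_artifacts(ses0$recording, ses0$events, list())
  expect_identical(out$recording$signal, ses0$recording$signal)
  expect_equal(nrow(out$annotations), 0)
  # a 10x RMS burst dominates the signal at its span
  pre_rms <- sqrt(mean(ses0$recording$signal["Cz", ]^2))
  out <- inject_artifacts(ses0$recording, ses0$events,
                          list(artifact_spec(2, "Cz", onset = 5,
                                             amplitude_factor = 10)))
  ann <- out$annotations
  expect_equal(nrow(ann), 1)
  span <- (ann$start_sample + 1):ann$end_sample
  expect_gte(max(abs(out$recording$signal["Cz", span])), 8 * pre_rms)
  # outside the span the signal is untouched
  expect_identical(out$recording$signal["Cz", -span],
                   ses0$recording$signal["Cz", -span])
  expect_identical(out$recording$signal["C1", ], ses0$recording$signal["C1", ])
})

test_that("artifact annotations round-trip through JSON", {
  cfg <- cfg_small(seed = 11, n_runs = 1, n_trials_per_run = 4,
                   artifact_specs = list(artifact_spec(1, "C1", 3),
                                         artifact_spec(3, "CPz", 6.5)))
  ses <- generate_session(cfg)
  path <- tempfile(fileext = ".json")
  write_ground_truth(ses$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$artifacts, ses$truth$artifacts)
  expect_equal(back$erds, ses$truth$erds)
  expect_identical(back$task, ses$truth$task)
})
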