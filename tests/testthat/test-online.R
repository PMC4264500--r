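test_that("the feedback rule is strict and artifact-gated", {
  rule <- feedback_rule()
  expect_equal(apply_feedback_rule(rule, 0.6, FALSE), "correct")
  expect_equal(apply_feedback_rule(rule, 0.5, FALSE), "pause")   # strictly > 50%
  expect_equal(apply_feedback_rule(rule, 0.49, FALSE), "pause")
  expect_equal(apply_feedback_rule(rule, 0.9, TRUE), "pause")    # artifact wins
  expect_equal(apply_feedback_rule(rule, 1.0, TRUE), "pause")
  expect_error(feedback_rule(threshold = 1.2), "threshold")
})

# one small causal session shared by the online tests
online_fixture <- function(seed = 51) {
  cfg <- cfg_small(seed = seed, n_runs = 3, n_trials_per_run = 12)
  ses <- generate_session(cfg)
  mont <- laplacian_montage(cfg$channel_labels)
  ep <- epoch(ses$recording, ses$events)
  feats <- extract_features(laplacian_derive(ep, mont))
  by_run <- lapply(1:3, function(r) {
    f <- feats
    keep <- which(f$run == r)
    f$values <- f$values[keep, , , , drop = FALSE]
    f$run <- f$run[keep]; f$task <- f$task[keep]; f$trials <- f$trials[keep]
    f
  })
  arm <- fit_inverse_filter(generate_resting(cfg, 30), mont)
  list(cfg = cfg, ses = ses, mont = mont, by_run = by_run, arm = arm)
}

test_that("recalibration uses up to the three most recent runs", {
  fx <- online_fixture()
  # one run -> leave-one-trial-out
  cfg <- cfg_small(seed = 52, n_runs = 1)
  ses <- generate_session(cfg)
  mont <- laplacian_montage(cfg$channel_labels)
  f1 <- extract_features(laplacian_derive(epoch(ses$recording, ses$events),
                                          mont))
  cal1 <- recalibrate(list(f1), seed = 2)
  expect_match(cal1$result$scheme, "leave-one-trial-out")
  expect_equal(cal1$n_runs_used, 1)
  # several runs -> nested block-wise; 4 runs -> only the last 3 used
  cal3 <- recalibrate(fx$by_run, seed = 2)
  expect_match(cal3$result$scheme, "block-wise")
  hist4 <- c(list(fx$by_run[[1]]), fx$by_run)   # duplicate oldest run
  cal4 <- recalibrate(hist4, seed = 2)
  expect_equal(cal4$n_runs_used, 3)
  expect_identical(cal4$result, cal3$result)    # runs 2-4 == original 1-3
  expect_error(recalibrate(list()), "no prior runs")
})

test_that("recalibration is deterministic", {
  fx <- online_fixture()
  a <- recalibrate(fx$by_run[1:2], seed = 5)
  b <- recalibrate(fx$by_run[1:2], seed = 5)
  expect_identical(a$model, b$model)
  expect_identical(a$result, b$result)
})

test_that("the online loop delivers mostly positive feedback on good sessions", {
  fx <- online_fixture()
  cal <- recalibrate(fx$by_run[1:2], seed = 3)
  ev3 <- with(fx$ses$events[fx$ses$events$run == 3, ],
              event_list(onset_sample, fs = fx$cfg$fs, label = label,
                         run = run))
  out <- simulate_online_run(fx$ses$recording, ev3, cal$model, cal$selected,
                             fx$arm, fx$mont)
  expect_equal(nrow(out), 12)
  expect_true(all(out$fraction >= 0 & out$fraction <= 1))
  expect_true(all(out$feedback[out$artifact] == "pause"))
  # implanted ERD + trained model: positive feedback above the 50% base
  expect_gt(mean(out$feedback == "correct"), 0.5)
  # transcript round-trips through JSON lines
  path <- tempfile(fileext = ".jsonl")
  write_transcript(out, path)
  lines <- lapply(readLines(path), jsonlite::fromJSON)
  expect_equal(length(lines), 12)
  expect_equal(vapply(lines, `[[`, 0, "fraction"), out$fraction)
})

test_that("feedback for a trial ignores everything after that trial", {
  fx <- online_fixture()
  cal <- recalibrate(fx$by_run[1:2], seed = 3)
  ev3 <- with(fx$ses$events[fx$ses$events$run == 3, ],
              event_list(onset_sample, fs = fx$cfg$fs, label = label,
                         run = run))
  full <- simulate_online_run(fx$ses$recording, ev3, cal$model, cal$selected,
                              fx$arm, fx$mont)
  # truncate the recording right after trial 2 and drop later events
  end2 <- ev3$onset_sample[2] + 12 * fx$cfg$fs
  rec2 <- fx$ses$recording
  rec2$signal <- rec2$signal[, seq_len(end2)]
  ev2 <- event_list(ev3$onset_sample[1:2], fs = fx$cfg$fs,
                    label = ev3$label[1:2], run = ev3$run[1:2])
  part <- simulate_online_run(rec2, ev2, cal$model, cal$selected,
                              fx$arm, fx$mont)
  expect_equal(part, full[1:2, ])
})

test_that("the session controller follows the significance policy", {
  fx <- online_fixture()
  res <- recalibrate(fx$by_run[1:2], seed = 3)$result
  good <- res; good$p_value <- 0.01
  bad <- res; bad$p_value <- 0.2
  expect_equal(session_controller(good)$action, "continue")
  expect_equal(session_controller(bad)$action, "stop")
  expect_equal(session_controller(bad, override = "continue")$action,
               "continue")
  expect_error(session_controller(NULL), "no session result")
})
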