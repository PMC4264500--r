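# epoch_set built directly from a waveform, one trial per row of `x`
manual_epochs <- function(x, fs = 128, cue_onset = 2, ref = c(1, 2)) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  dat <- array(x, c(nrow(x), 1, ncol(x)), dimnames = list(NULL, "Cz", NULL))
  structure(list(data = dat, fs = fs, labels = "Cz",
                 task = rep("sport", nrow(x)), run = rep(1L, nrow(x)),
                 rejected = logical(nrow(x)),
                 window = c(0, ncol(x) / fs), cue_onset = cue_onset,
                 reference_window = ref),
            class = "epoch_set")
}

test_that("the default band grid is 35 overlapping 2-Hz bands", {
  g <- band_grid()
  expect_equal(nrow(g), 35)
  expect_equal(g$low, 6 + 0:34)
  expect_equal(g$high, 8 + 0:34)
})

test_that("band power of a pure sinusoid is A^2/2", {
  fs <- 128
  t <- seq_len(12 * fs) / fs
  for (A in c(1, 5)) {
    ep <- manual_epochs(A * sin(2 * pi * 10 * t), fs)
    pw <- band_power_trials(ep, c(9, 11))
    # skip settling zones at the edges
    expect_equal(mean(pw[1, 1, (2 * fs):(10 * fs)]), A^2 / 2,
                 tolerance = 0.02)
  }
  expect_true(all(band_power_trials(manual_epochs(0 * t), c(9, 11)) == 0))
})

test_that("an amplitude step halves power by its square", {
  fs <- 128
  t <- seq_len(12 * fs) / fs
  amp <- ifelse(t <= 6, 2, 1)
  ep <- manual_epochs(amp * sin(2 * pi * 10 * t), fs)
  pw <- band_power_trials(ep, c(9, 11), causal = TRUE)
  # steady state: >= 2 s after onset / step (filter + 1-s settling)
  before <- mean(pw[1, 1, (3 * fs):(5.5 * fs)])
  after <- mean(pw[1, 1, (9 * fs):(12 * fs)])
  expect_equal(after / before, 0.25, tolerance = 0.05)
})

test_that("bands at or above Nyquist are rejected", {
  ep <- manual_epochs(stats::rnorm(1280), fs = 128)
  expect_error(band_power_trials(ep, c(60, 64)), "Nyquist|outside")
})

test_that("ERDS maps recover implanted power changes", {
  # ERD: amplitude factor 0.5 -> -75%; ERS: sqrt(2) -> +100%
  for (case in list(c(0.5, -75), c(sqrt(2), 100))) {
    cfg <- cfg_small(seed = 31, oscillation_specs = list(
      oscillation_spec("Cz", 10, activity_amplitude_factor = case[1])))
    se <- small_epochs(cfg)
    m <- compute_erds_map(se$epochs, channels = "Cz", seed = 5)
    bi <- which(m$grid$low == 9)
    px <- mean(m$values["Cz", bi, m$times > 3 & m$times < 11.5])
    expect_equal(px, case[2], tolerance = 0.08 * max(abs(case[2]), 50))
    # the implanted pixel is flagged significant throughout
    expect_gte(mean(m$mask["Cz", bi, m$times > 3 & m$times < 11.5],
                    na.rm = TRUE), 0.95)
  }
})

test_that("ERDS values are scale invariant and ~0 in the reference window", {
  cfg <- cfg_small(seed = 32, n_runs = 1)
  se <- small_epochs(cfg)
  m1 <- compute_erds_map(se$epochs, channels = "Cz", seed = 5)
  ep2 <- se$epochs; ep2$data <- ep2$data * 3.7
  m2 <- compute_erds_map(ep2, channels = "Cz", seed = 5)
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
  expect_identical(m1$mask, m2$mask)
  ref_px <- m1$values["Cz", , m1$times >= 1 & m1$times < 2]
  expect_lt(abs(mean(ref_px)), 3)
  expect_gte(min(m1$values), -100)
})

test_that("maps and masks are reproducible under a fixed seed", {
  cfg <- cfg_small(seed = 33, n_runs = 1, n_trials_per_run = 8)
  se <- small_epochs(cfg)
  m1 <- compute_erds_map(se$epochs, channels = "Cz", seed = 9, B = 300)
  m2 <- compute_erds_map(se$epochs, channels = "Cz", seed = 9, B = 300)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$mask, m2$mask)
})

test_that("the bootstrap handles degenerate inputs as specified", {
  # zero trial variance: interval has width zero; mask = (value != 0)
  X <- matrix(2, 8, 3); X[, 3] <- 1
  r <- rep(1, 8)
  bs <- bootstrap_significance(X, r, B = 200, seed = 1)
  expect_equal(bs$estimate, c(100, 100, 0))
  expect_identical(bs$mask, c(TRUE, TRUE, FALSE))
  expect_equal(bs$lower, bs$upper)
  # zero reference power is an error, not infinity
  expect_error(bootstrap_significance(matrix(1, 8, 2), rep(0, 8),
                                      B = 200, seed = 1), "reference power")
  expect_error(bootstrap_significance(matrix(1, 3, 2), rep(1, 3),
                                      B = 200, seed = 1), ">= 5 trials")
  expect_error(bootstrap_significance(matrix(1, 8, 2), rep(1, 8),
                                      B = 50, seed = 1), "B must be")
})

test_that("bootstrap intervals are sane on a known mean shift", {
  set.seed(8)
  n <- 45
  r <- stats::rchisq(n, df = 8)
  X <- cbind(r * 0.25 * stats::rchisq(n, df = 8) / 8,  # true ERDS -75%
             r * stats::rchisq(n, df = 8) / 8)         # true ERDS 0%
  bs <- bootstrap_significance(X, r, B = 1000, seed = 3)
  # column 1: deep ERD, interval below zero and around the true -75%
  expect_equal(unname(bs$estimate[1]), -75, tolerance = 0.15)
  expect_lt(bs$upper[1], 0)
  expect_true(bs$lower[1] < -75 && -75 < bs$upper[1])
  expect_true(bs$mask[1])
  # column 2: the reference itself, interval straddles zero
  expect_true(bs$lower[2] < 0 && bs$upper[2] > 0)
  expect_false(bs$mask[2])
})

test_that("a map needs at least five unrejected trials", {
  cfg <- cfg_small(seed = 34, n_runs = 1, n_trials_per_run = 6)
  se <- small_epochs(cfg)
  ep <- se$epochs
  ep$rejected[1:3] <- TRUE
  expect_error(compute_erds_map(ep, channels = "Cz", seed = 1, B = 200),
               ">= 5")
})
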