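---
title: "Detecting mental imagery from cue-based EEG: methods and design notes"
author: "imagerybci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mental imagery from cue-based EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imagerybci)
```

## The problem

Patients with disorders of consciousness (minimally conscious state,
unresponsive wakefulness) may be able to follow commands mentally while
showing no overt behaviour.  A bedside EEG protocol probes this with
cue-based trials: a beep marks the trial start, a verbal cue at t = 2 s
instructs the patient to perform a mental task (kinesthetic sport imagery,
spatial navigation, or attempted foot movement), and the task is sustained
to the end of the 12-s trial.  Tasks are run in blocks: three runs of 15
trials each, separated by random 4–6 s pauses, giving 45 trials per task.
Sustained motor imagery or attempted movement desynchronizes sensorimotor
rhythms — band power over central cortex drops relative to the pre-cue
reference interval (second 1–2 of the trial).  That event-related
desynchronization (ERD; its power-increase counterpart is ERS) is the
signature everything in this package quantifies.

Two questions follow from such recordings:

1. **Is there a task-related EEG change at all, and where?**  Answered by
   ERD/ERS time–frequency maps with pixel-wise bootstrap significance.
2. **Can single trials be detected well enough for communication?**
   Answered by log band-power LDA classification under nested block-wise
   cross-validation, and — when the estimate is promising — a simulated
   online feedback loop.

Because no patient data are distributable, the package ships a synthetic
session generator with exact ground truth; every stage of the pipeline is
validated against it.

## The synthetic generator

`generate_session()` emulates the paradigm's physical layout exactly
(trial length, cue latency, reference window, runs, pauses) and a
deliberately minimal signal model:

* **Background**: per-channel Gaussian noise shaped to a 1/f^a spectrum in
  the frequency domain (exact spectral control), flattened below 0.5 Hz to
  mimic the acquisition high-pass.  Default RMS 5 µV, a = 1.
* **Rhythms**: an `oscillation_spec()` implants a narrowband Gaussian
  process (Gaussian spectral bump, FWHM = bandwidth) at one channel —
  narrowband *noise*, not a sinusoid, so band power fluctuates from trial
  to trial the way real mu/alpha rhythms do, which is what the bootstrap
  and the classifier actually have to cope with.  The default is a 10-Hz,
  8 µV RMS central rhythm at Cz: a prominent but realistic mu rhythm,
  ~13 dB above the background in its band.
* **ERD/ERS**: during each trial's modulation window (default cue onset to
  trial end, since the instruction is to sustain the task) the rhythm's
  amplitude is scaled by a factor; 0.5 by default, i.e. an implanted ERD
  of (0.5² − 1)·100 = −75%.  Ramps are 0.25-s raised cosines to avoid
  spectral splatter.  Ground truth records the implanted percentage.
* **Artifacts**: `artifact_spec()` adds Hann-windowed bursts of 2–40 Hz
  noise whose peak is `amplitude_factor` × the channel RMS — the
  morphology of movement/EMG transients at the scale that matters for a
  threshold detector.  Spans are annotated sample-exactly.

What the generator does **not** model: auditory evoked responses to the
cue, volume conduction (each rhythm lives on one electrode), realistic
EOG/EMG spectra, non-stationary vigilance drifts.  Tests passing on this
model therefore demonstrate that the *algorithms* are correct and
calibrated, not that the pipeline will perform at any particular level on
patient EEG.

Identical configuration + seed reproduces sessions bit-exactly; every
stochastic routine in the package takes an explicit seed.

## Sampling rates

Acquisition is simulated at 512 Hz (32 channels).  All band-power analysis
operates at 128 Hz after `downsample()` (8th-order Butterworth anti-alias
at 80% of the new Nyquist, zero-phase offline, causal for the online
chain).  Two reasons: every band of interest ends below 42 Hz, and narrow
2-Hz Butterworth band-passes are much better conditioned at 128 Hz
(pole radii ~0.98 vs ~0.996 at 512 Hz).  This is an analysis choice, not a
property of the data; `epoch()` and the I/O layer work at any rate.

## ERD/ERS maps

`compute_erds_map()` follows the classical band-power recipe: per trial
and channel, band-pass filter (4th-order Butterworth, applied
forward–backward so map latencies are not smeared), square, smooth with a
0.25-s moving average, then average over trials.  The map value at a pixel
is `ERDS% = (A − R)/R × 100` with `A` the trial-averaged power at that
(channel, band, time) and `R` the trial-averaged power in the reference
interval.  The default grid is 35 overlapping 2-Hz bands stepped 1 Hz from
6 Hz.  Power is read every 1/16 s — after 0.25-s smoothing the power
envelope has no content above ~4 Hz, so this costs nothing.

Significance is a t-percentile bootstrap (default B = 1000, α = 0.05):
trials are resampled with replacement, the ERDS statistic is studentized
with a delta-method standard error of the ratio-of-means (recomputed
inside every resample), and a pixel is flagged when the two-sided
(1 − α) studentized interval excludes zero.  The same resamples are used
for all pixels, so masks are spatially coherent and reproducible under a
fixed seed.  Implementation notes:

* The mask is decided directly from the empirical tails of the
  studentized resamples (equivalent to the interval test up to
  interpolation); explicit interval endpoints use type-7 quantiles.
* Zero trial variance degenerates gracefully: interval width 0, pixel
  significant iff its value is non-zero.  A zero reference power is an
  error, not an infinity.
* Pixels within 0.5 s of the trial edges are masked `NA`: residual filter
  settling, not ERD.
* No correction across pixels — maps display pixel-wise significance, and
  the documentation says so.  On null sessions the significant-pixel
  fraction sits at the nominal 5% (checked over 20 seeds in the tests).

## Artifact rejection (online branch)

Offline analyses in this field often rely on ICA with visual component
selection; that is out of scope here because it is not algorithmic.  The
online-capable detector is the inverse-filter method: fit an AR model per
orthogonal-Laplacian channel on 1–2 min of resting EEG, apply the
whitening (inverse) filter to incoming trials, and flag a trial when the
absolute prediction error exceeds **exactly 5 × the residual RMS** from
the resting fit on any monitored channel.  Transients are poorly predicted
by the resting model and explode the innovation.  Defaults: AR order 10,
Burg's method (stable on short segments), all derivable channels
monitored, single-sample exceedance (the strictest reading; a minimum
run-length is configurable).  On synthetic data, 10×RMS bursts are caught
in 100% of trials and clean-trial false rejection is below 3%.

The Laplacian montage is Hjorth-style: each channel minus the mean of its
orthogonal nearest neighbours on the 10-10 grid (up to four).  Edge
channels keep ≥2 available orthogonal neighbours or are excluded (C5/C6 in
the default 32-channel montage).  Only the grid topology matters; the
label set is configurable.

## Features and classification

`extract_features()` computes log band power in the five canonical bands
(θ 4–7, α 7–13, β_low 13–19, β_mid 19–25, β_high 25–30 Hz): causal
band-pass, squaring, causal 1-s moving average computed sample by sample,
log.  The 12-s trial is tiled into twelve 1-s segments and the smoothed
log power is read at each segment midpoint (0.5, 1.5, …, 11.5 s).  The
segment at 1–2 s is the reference class; every post-cue segment is a
candidate activity class.  Features are strictly causal — a value at a
midpoint uses no later samples — so offline and online features are the
same quantity.

Classification is reference-vs-activity with a 1-D LDA per
(channel, band, segment) triple: each trial contributes one reference and
one activity sample.  `train_lda()` is the standard pooled-covariance
discriminant `w = S⁻¹(μ₁ − μ₀)` with the boundary at the class midpoint
and shrinkage toward a scaled identity when the problem is small or
ill-conditioned (the 1-D case never needs it, but the model is general).

`nested_blockwise_cv()` guards the selection search: the outer loop leaves
one block (run of 15 trials) out; the inner loop runs 10 repetitions of
10-fold CV on the training blocks only, with fold assignments drawn once
and held constant across the whole grid so all triples are compared on the
same splits; the best triple by inner accuracy is refit on the training
blocks and evaluated on the held-out block; outer confusion matrices are
summed (micro-averaged) into one accuracy.  Ties in selection break to the
earlier segment, then lower band, then channel order — deterministic, and
favouring earlier detection.  `loto_cv()` is the leave-one-trial-out
variant for single-run (initial-calibration) data.  The reported selected
triple is the one the same inner procedure chooses on all blocks — the
triple an online session would continue with; per-fold selections are kept
in the result for audit.

Session significance is a one-sided exact binomial test of the
micro-averaged correct count against chance 0.5, reported with the
conventional 0.05/0.01 tags.  This matches the field's reporting, but it
is *uncorrected for the selection search* over channels × bands ×
segments; `permutation_significance()` reruns the whole nested procedure
on label-permuted feature sets for a search-aware p-value.  (On null data
the binomial call is in practice conservative here, because inner
selection overfits permuted training blocks and depresses outer accuracy
below chance.)  The null model permutes the segment axis within each
trial, making the two classes exchangeable while preserving the spatial
and trial structure.

## The online feedback loop

`simulate_online_run()` replays a run through a fully causal chain:
causal band-pass and 1-s moving average on the selected Laplacian
channel, per-sample LDA prediction across the imagery period (cue onset to
trial end by default; the paradigm does not fix the span, so it is
configurable), with the artifact detector running concurrently.  Feedback
is *biased*: the positive message is delivered only when the classifier
predicted the imagery class for **strictly more than 50%** of the imagery
period and the trial is artifact-free; otherwise — including every
artifact-flagged trial — the neutral pause message is given.  Because only
correct trials trigger positive messages, the simulator records the true
per-trial correct-prediction fraction alongside the delivered message, so
the feedback bias is quantifiable.  No smoothing is applied to the
per-sample predictions before the 50% rule (the rule taken literally);
smoothing can be added upstream if wanted.

`recalibrate()` implements the run-by-run classifier update: features from
up to the three most recent runs are concatenated, selection and the
cross-validated estimate are recomputed (leave-one-trial-out when only one
run exists, nested block-wise otherwise), and the classifier is refit at
the selected triple.  `session_controller()` is the deterministic
continue/stop policy on the latest p-value, with a manual override hook in
place of unquantifiable clinical judgement (fatigue, vigilance).

## Numerical and design choices, in one place

* 0-based sample indexing in event files; half-open `[start, stop)`
  windows, so a 12-s trial at 512 Hz is exactly 6144 samples and 1-s
  segments tile it exactly.
* EDF I/O uses the 16-bit EDF format with a ±200 µV physical range;
  events travel in a companion CSV rather than EDF+ annotations
  (deterministic round-trips).  A trailing partial data record is
  zero-padded, with the true sample count noted in the reserved header
  field so the reader can trim it.
* Band-pass filters: 4th-order Butterworth; zero-phase (filtfilt) for
  maps, causal for features and the online chain.  The compiled filter
  core reproduces `signal::filter`/`signal::filtfilt` to ~1e-10 and is
  only a speed path.
* Log features are floored at 1e-12 before the log; clamping is counted
  and warned about (it cannot occur for non-degenerate signals).
* Problem sizes in the tests and the acceptance script: full 45-trial
  sessions; 32-channel montages where channel topology matters (parameter
  recovery), focal 3–9 channel montages where it does not (bootstrap
  calibration, artifact rates); 20 seeds/permutations for Monte-Carlo
  rates.  These sizes make the whole validation run in minutes on one
  core while keeping the Monte-Carlo standard errors well inside the
  asserted bands.

## Known limitations

* The generator's simplicity is deliberate; see above for what it omits.
* The exact binomial session p-value ignores the selection search (use the
  permutation variant when that matters).
* The bootstrap's delta-method studentization assumes the ratio-of-means
  is smooth in the resampled moments; with fewer than ~10 trials prefer
  more trials over trusting the interval.
* Multi-class task-vs-task discrimination is out of scope (the protocol
  classifies each task against its own reference interval).
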