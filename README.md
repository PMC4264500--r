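# imagerybci

Detection of mental imagery and attempted movements from cue-based EEG,
for brain–computer interface work with patients with disorders of
consciousness (minimally conscious state, unresponsive wakefulness).  The
package is aimed at researchers who need the full bedside protocol as
tested, reproducible code: paradigm simulation with ground truth, ERD/ERS
mapping with bootstrap significance, band-power LDA classification under
nested cross-validation, online-capable artifact rejection, and a
simulated biased-feedback loop.

## What it computes

In a cue-based trial (beep at t = 0, verbal task cue at t = 2 s, trial
length 12 s, reference interval 1–2 s), sustained motor imagery or
attempted movement desynchronizes sensorimotor rhythms.  The package
quantifies this two ways:

**ERD/ERS maps.**  For band power *A* at a (channel, band, time) pixel and
reference-interval power *R* (both trial-averaged),

    ERDS% = (A − R) / R × 100

computed over 35 overlapping 2-Hz bands (6–40 Hz, 1-Hz step), with
pixel-wise significance from a t-percentile bootstrap over trials
(studentized resampling, interval excludes 0 at α = 0.05).

**Single-trial classification.**  Log band power (band-pass → square →
causal 1-s average → log) in the canonical bands θ 4–7, α 7–13,
β 13–19/19–25/25–30 Hz, one value per 1-s segment midpoint; an LDA
`w = S⁻¹(μ_act − μ_ref)` separates the reference segment from a post-cue
segment; the best (Laplacian channel, band, segment) triple is chosen by a
nested block-wise cross-validation (10 × 10-fold inner, leave-one-block-out
outer, micro-averaged confusion matrices) with an exact binomial test of
the accuracy against chance.  An online loop recalculates the classifier
after every run from up to three previous runs and delivers positive
("biased") feedback only when the classifier predicts the imagery class
for strictly more than 50% of the imagery period in an artifact-free trial.

Artifacts are flagged by inverse (whitening) AR filtering of the
orthogonal Laplacian derivations, calibrated on resting EEG, with the
detection threshold at exactly 5 × the resting residual RMS.

Because the underlying clinical recordings are not distributable, the
package includes a first-class synthetic session generator
(`generate_session()`) that reproduces the paradigm timing and implants
rhythms, ERD/ERS of known depth, and annotated artifacts — every pipeline
stage is validated against that ground truth.

## Worked example

```r
library(imagerybci)

cfg <- simulation_config(seed = 2026)   # 32 ch, 512 Hz, 3 runs x 15 trials,
ses <- generate_session(cfg)            # -75% ERD implanted at Cz, 10 Hz
ses$recording
#> <eeg_recording> 32 channels x 386323 samples @ 512 Hz (754.5 s)
#>  channels: F3 F1 Fz F2 F4 FC3 FC1 FCz ...

rec <- downsample(ses$recording, 4)     # analyse at 128 Hz
ep  <- epoch(rec, resample_events(ses$events, 4, 512))

map <- compute_erds_map(ep, channels = "Cz", seed = 1)
map
#> <erds_map> 1 channels x 35 bands x 192 times, 45 trials
#>  ERDS range [-99.6, 217.6]%; 16.0% of pixels significant (alpha = 0.05)
bi <- which(map$grid$low == 9)
mean(map$values["Cz", bi, map$times > 3 & map$times < 11.5])
#> [1] -75.97  # the implanted -75% ERD, recovered

mont  <- laplacian_montage()
feats <- extract_features(laplacian_derive(ep, mont))
nested_blockwise_cv(feats, seed = 1)
#> <session_result> nested block-wise CV
#>  79% (Cz, alpha, 0.01)  [selected segment 8, midpoint 7.5 s]
#>            predicted
#> truth       reference activity
#>   reference        36        9
#>   activity         10       35
```

The session result reads like the field's convention — accuracy, then the
selected (channel, band) and the significance level: the pipeline found
the implanted rhythm at Cz in the alpha band and classifies single trials
at 79% against the 50% chance level (exact binomial p ≤ 0.01).
`plot(map, "Cz")` draws the time–frequency map with significance dots.

## Scope

ICA-based offline artifact removal (which requires visual component
inspection), task-vs-task multi-class discrimination, source modelling and
real-time hardware integration are out of scope.  See the vignette
(`vignettes/erds-imagery-pipeline.Rmd`) for the methods, their
assumptions, and the design decisions.
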