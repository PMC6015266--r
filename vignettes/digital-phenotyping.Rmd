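---
title: "Digital phenotyping of stress and mental health: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping of stress and mental health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wearstress` re-implements, as a tested and reusable package, an analysis
pipeline for month-long ambulatory studies in which college students enrolled
in semester cohorts wear a wrist sensor (skin conductance SC in µS, skin
temperature ST in °C, 3-axis acceleration), carry a phone that logs calls,
SMS, screen events and location, keep twice-daily diaries, and complete the
Perceived Stress Scale (PSS, 0–40) and the SF-12 Mental Component Summary
(MCS) before and after the study. The pipeline extracts a large named feature
matrix from these streams, builds high/low stress and mental-health groups
from the post-study scores, and asks how well the feature modalities classify
those groups under leave-one-cohort-out cross-validation. Because no such
cohort dataset is publicly deposited, the package ships a synthetic cohort
generator that reproduces the statistical structure the analysis assumes;
every stage is exercised end to end on generated data.

## Signal processing model

**Skin conductance.** Raw SC is low-pass filtered with a 32nd-order
Hamming-window FIR filter at a 0.4 Hz cutoff, applied forward and backward
(zero phase). Two implementation details matter and are documented here
because they are easy to get wrong: the FIR design returned by `signal::fir1`
is renormalized to exact unit DC gain (`b / sum(b)`), and the series is
padded by odd reflection (length `3 × order`) before the two filter passes so
that edges carry no startup transient; a constant input is reproduced exactly.
The filter is specified by cutoff in Hz and fixed order 32 regardless of
sampling rate; the rate must exceed twice the cutoff.

**SC response peaks.** Peaks are detected on the filtered, *non-normalized*
signal: the discrete first derivative is compared against a slope threshold
of 0.02 µS/s, and each maximal contiguous suprathreshold run yields one event,
timestamped at the run onset. Onset timestamping makes the assignment of an
event to a 30-s epoch unambiguous. A brute-force scan oracle (explicit loop
over first differences) verifies the detector in the test suite.

**Plausibility masks.** Samples outside 0.01–30 µS (SC) or 20–42 °C (ST) are
masked, bounds inclusive, and combined with the device's own worn/valid flag
by logical AND. The published artifact classifier for SC is out of scope
here; the mask provider is pluggable, and the range mask is the default
provider.

**Epochs and windows.** Features are accumulated in 30-second epochs aligned
to local midnight, inside four clock windows: late night (00–03), day
(09–18), night (18–24), and the per-day sleep episode; all intervals are
half-open `[start, end)` local time. An epoch belongs to a window iff its
start time does. Per-epoch AUC uses the trapezoidal rule with right-endpoint
continuation (the first sample of the next epoch closes the integral) so a
constant 2 µS epoch integrates to exactly 60 µS·s; epochs with missing
samples fall back to `mean(valid) × 30 s`, and epochs under 50 % valid are
missing. A participant-day-window contributes only if at least 50 % of its
expected samples are valid (configurable `min_valid_frac`), and across-day
aggregates (mean, median, SD) require at least two contributing days. Whether
amplitude statistics use filtered or raw SC is not fixed by convention; this
package computes them on the filtered, masked signal.

**Daily normalization.** Because SC amplitude differs strongly between
individuals, a second feature family uses per-day min–max normalized SC;
degenerate (constant) days map to 0.

## Sleep Regularity Index

With minute-resolution states `s(t) = +1` (wake) / `−1` (sleep), the index is

```
SRI = −100 + 200 · P[ s(t) = s(t + 1440 min) ]
```

averaged over all valid pairs; pairs with a missing state are excluded
pairwise, not imputed. The three anchors that pin down the normalization are:
a perfectly periodic sleeper scores exactly 100, independent random states
score 0 in expectation, and alternating 24 h of sleep with 24 h of wake
scores −100. This `−100 + 200·agreement` form is adopted precisely because it
reproduces all three anchors.

When the index is computed from per-day episodes, the state vector is trimmed
to the sleep-bracketed observation span — from the first recorded bedtime to
the last recorded wake. The minutes before the first bedtime and after the
last wake are unobserved; scoring them as wake would penalise even a
perfectly periodic sleeper, because the record's first morning would disagree
with every later morning.

Bedtime statistics use a circular reference axis anchored at 18:00 (value 360
≡ midnight): student bedtimes concentrate between 18:00 and 12:00, so this
axis avoids the midnight wrap without circular-moment machinery, keeps the
feature continuous for the classifiers, and makes "SD of bedtime" well
defined. When synthetic sleep episodes with efficiency < 1 are converted to
minute states, the implied within-episode wake minutes are placed uniformly
at random under a fixed seed; only aggregate statistics depend on that
placement, and weakly.

## Phone and mobility features

Call, SMS and screen events are summarized per day in three windows (full
day, late night, night) and aggregated across days. SMS logs are instantaneous
events, so "SMS duration" is defined as the span of a *session*: consecutive
messages with the same contact separated by less than 5 minutes (configurable).
Message counts and unique-contact counts still use raw messages. A screen
bout runs from an `on` event to the next `off`; an unpaired trailing `on` is
closed at the next local midnight. Timestamps-of-day are encoded as minutes
since the window start, so no wrap occurs inside any of the three windows.
Days without events in a window are missing for that window, not zero.

Mobility works on a planar meter grid (the generator emits planar
coordinates; a geodesic mode would only be needed for real latitude/longitude
input and is deliberately not the default, which keeps the test oracles
exact). Per day: total distance (sum of consecutive-fix displacements); the
"5-min distance", defined here — no standard definition exists — as the mean
displacement between successive non-empty 5-minute bin centroids; and radius,
the maximum distance of any fix from the day centroid. Routineness is scored
by a full-covariance Gaussian mixture fitted to the participant's entire
trace with the number of components chosen by BIC over 1–8 (`mclust`). The
day score is the *mean per-fix* log density (a total would confound
routineness with fix count). `mclust`'s model-based hierarchical
initialization is deterministic, so repeated fits are identical without seed
management or restarts.

## Group construction

High/low stress groups split at post-study PSS ≥ 16 (alternate cutoff 14
supported); the larger class is randomly downsampled, without replacement and
under a recorded seed, to the smaller class's size, making both priors 0.5 so
a random classifier sits at 50 % accuracy. Mental-health groups take the
extreme tails of the post-study MCS (≥ 50 good mental health, ≤ 29.4 low; or
symmetric quantile tails, ties kept then trimmed by score order; or a median
split). The extreme tails are near-balanced by construction, so no
downsampling is applied there.

## Classification protocol

Evaluation is leave-one-cohort-out: each enrollment cohort is held out in
turn, and everything fitted — the median imputer, the standardizer, the
feature prefilter, the feature selector, the hyperparameters and the model —
is computed on the remaining cohorts only. Within a training fold: a Welch
two-sample t-test per feature keeps the 100 smallest-p features; sequential
forward selection then adds up to five features greedily, scoring each
candidate by inner stratified 10-fold CV accuracy of an SVM-RBF jointly
grid-searched over cost and kernel width; the returned set is the prefix with
the best inner accuracy (ties prefer fewer features, then lower prefilter
rank). The SVM-linear family reuses the same selection machinery (selection
is always RBF-scored) and tunes its own cost on the same inner folds; LASSO
skips prefilter and selection and picks its penalty by inner 10-fold CV on
the full standardized feature set (50 log-spaced penalties). Out-of-fold
predictions from all folds are concatenated before computing accuracy, its
adjusted-Wald (Agresti–Coull) 95 % CI, and F1 with the high group as the
positive class; concatenation means the overall accuracy is exactly the
fold-size-weighted mean of per-fold accuracies, which the tests assert.

Default grids (cost ∈ {0.1, 1, 10, 100}, gamma ∈ {10⁻³…10}) are package
choices — no standard values exist for this protocol — and are configurable;
the test suite uses reduced grids. Missing feature values are imputed by
training-fold medians and features standardized by training-fold mean/SD
before any scale-sensitive model; both are fitted strictly inside the fold.
An automated leakage guard plants a feature informative only within one
held-out cohort and asserts it can influence neither the prefilter nor the
selection for that fold.

## The synthetic cohort generator

A latent stress trait `z ~ N(0,1)` per participant drives everything. The
questionnaire model is

```
PSS_post = 17.1 + b1·z + s1·e      (total SD 6.5)
MCS_post = 40.4 − b2·z + s2·e′     (total SD 10)
cor(PSS, MCS) = −(b1·b2)/65
```

The package resolves the loadings **asymmetrically**: the PSS residual SD is
fixed at 2 score points — the trait *is* perceived stress, and a short-horizon
repeat administration of the PSS is about that reliable — giving
`b1 = √(6.5² − 2²) ≈ 6.19`, and `b2 = 0.71·65/b1 ≈ 7.46` then follows in
closed form so the PSS–MCS correlation hits its −0.71 target (verified over
20 seeds within ±0.05). A symmetric split of the loadings would bury the
group labels in questionnaire noise: the conditional variance of `z` given
the PSS group would cap leave-one-cohort-out accuracy near 80 % *no matter
how large a signal effect is injected*, which would make effect-recovery
checks meaningless. Pre-study scores load on the same trait with weights
solved to correlate about 0.6 with the post scores, at means 15.0 (PSS) and
44.4 (MCS).

Five behavioural families carry configurable standardized effects of `z`:
daytime SC peak rate (multiplicative on a base of 0.30 peaks/min by day,
0.18 evening, 0.10 late night), nap rate (Poisson, base 0.45/day), mobility
radius (anchor spread, base 700 m, loading negative: higher stress, smaller
radius), screen-bout duration, and bedtime jitter (base SD 22 min). Each
family also carries idiosyncratic between-participant noise so that zero
effect sizes give exchangeable groups; null-cohort tests confirm the FDR
pipeline then finds nothing.

The SC stream is a bounded tonic random walk (logistic-squashed, so its slope
stays far below the peak threshold) plus phasic events — Poisson onsets
convolved with a kernel rising over ~4 s and decaying over ~40 s, amplitudes
0.25–0.8 µS — plus Gaussian measurement noise with SD 0.003 µS, the scale of
the device quantization. The noise floor matters: the first difference of the
filtered trace must stay well below 0.02 µS/s between true events, otherwise
the slope detector counts noise rather than physiology, which defeats the
detector at the low sampling rates used for fast tests. Locations are planar
anchors (home plus 2–3 routine places at the participant's radius) with 30 m
GPS noise; diaries are generated consistent with the ground-truth sleep
episodes (no AM/PM errors — diary corruption is out of scope for the default
generator). None of the raw-signal distributions follow any published claim;
they are package design choices tuned for face plausibility, not fits to
data.

What generated data cannot show: real SC artifacts beyond range violations
(pressure artifacts, electrode drift), circadian physiology in ST/ACC beyond
a fixed sinusoid, socially structured behaviour between participants, or
measurement idiosyncrasies of any particular device. Passing tests therefore
demonstrate correctness of the *pipeline* under the assumed data model, not
field validity of the features.

## Numerical choices and degenerate inputs

* Sampling rate is configurable; `30 × rate` must be an integer so epochs
  tile exactly. The study-like default is 8 Hz and 30 days; the test suite
  runs at 1 Hz over 2–3-day spans (and 1/30 Hz where only outcomes and event
  logs matter), sizes chosen once as the package's own desk-scale conditions.
* Degenerate days in daily normalization map to 0; zero-variance features are
  skipped and flagged by the group tests; a class made empty by a cutoff is a
  labeling error, not an `NA`.
* Ties in forward selection resolve toward fewer features, then lower
  prefilter rank; equal-p features keep `order()`'s stable ordering.
* Datasets round-trip bit-exactly through CSV: doubles are written in
  shortest round-trip representation and re-read with the C library's exact
  `strtod` parser (base `read.csv`), which the tests assert via `identical()`.
* The recovery benchmark in the acceptance suite (n = 100, 5 cohorts, SC-peak
  effect 1.5 SD) and its zero-effect control are run at 1 Hz with reduced SVM
  grids; the planted effect is recovered at ≥ 85 % held-out accuracy while
  the control sits at chance.

## Known limitations

The artifact classifier of the original instrumentation is replaced by range
masks behind a pluggable interface; actigraphy sleep scoring is replaced by
ground-truth (or precomputed) sleep states; e-diary administration tooling is
out of scope. Headline accuracies from any real cohort are not reproducible
here — the cohort data are not deposited — and the package makes no claim
about them: its guarantees are the self-contained anchors and the
property-based suites described above.
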