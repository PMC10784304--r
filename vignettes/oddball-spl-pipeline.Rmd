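---
title: "Methods: the sound-level oddball BCI pipeline"
author: "oddvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sound-level oddball BCI pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An auditory oddball brain-computer interface for automatic volume
control presents short bursts of white noise at different sound
pressure levels (50, 60, 70 dB) while the listener attends to one
level (the *target*). Attended rare stimuli evoke a P300 — a positive
event-related potential (ERP) peaking roughly 300–500 ms after onset,
maximal over central-parietal scalp — and a classifier that detects the
P300 on single trials can tell which level the listener wants the
system to act on. `oddvol` implements the complete desk-side analysis
for such studies: a synthetic-EEG generator that emulates the paradigm,
the fixed preprocessing chain, ERP block statistics, nested
cross-validated classification with trial averaging, and study-level
reporting, so every stage can be exercised and tested without any data
download.

Two designs are built in. In the *1-Target* design 80 % of trials are
60-dB standards and 20 % are 70-dB targets. In the *2-Target* design
trials are 20 % at 50 dB, 60 % at 60 dB and 20 % at 70 dB; the target
is 70 dB in sessions 1–10 and 50 dB in sessions 11–20, while the 60-dB
standards are to be ignored ("frequent"). A study comprises 20 sessions
of 70 one-second trials (100-ms stimulus, 900-ms rest), recorded from
64 electrodes of the extended 10–20 system at 256 Hz.

## The synthetic generator

`simulate_session()` builds each session as *background noise + evoked
responses*:

* **ERP components.** Each component is a Gaussian bump
  `polarity · A · exp(−(t − latency)² / 2w²)` spread over the scalp by a
  Gaussian topography in a flat 2-D electrode layout. The defaults are
  an auditory N1 (−2 µV, 100 ms, 30 ms width, fronto-central) and a
  P300 (400 ms, 60 ms width, centro-parietal) at 8 µV for targets and
  1 µV for nontargets/standards. These values reproduce the
  qualitative morphology of sound-level oddball grand averages (a
  target-specific positivity near 400 ms of roughly 10 µV at Cz).
* **Loudness dependence.** Auditory evoked potentials grow with sound
  level; the per-level gains default to 0.7 / 1.0 / 1.3 for
  50 / 60 / 70 dB. The magnitudes are free modelling choices, not
  measured values.
* **Habituation.** Session *s* is scaled by `h^(s−1)`; the default
  `h = 0.99` encodes the mild amplitude decline seen over long
  recordings, and `h = 0.9` gives a pronounced decline for
  habituation-sensitivity checks.
* **Participants.** Each participant multiplies all amplitudes by a
  lognormal factor (σ = 0.2 on the log scale).
* **Noise.** Per channel: 1/f pink noise (spectral exponent α = 1) at
  15 µV RMS, a 10-Hz alpha sinusoid (3 µV, random phase), and a 2-µV
  white floor. The 15-µV RMS was chosen once as a realistic EEG
  background that leaves single-trial decoding clearly above chance
  but well below ceiling (≈ 0.6–0.65 balanced accuracy with all 64
  channels), so that chance-level and monotonicity properties are
  observable.

Stimulus schedules (`make_schedule()`) apportion the level fractions
over the 70 trials by largest-remainder rounding — so the stated
percentages are met *exactly* (14/56 and 14/42/14) — and shuffle the
order uniformly under a seed. "Pseudorandom" is interpreted as an
unconstrained seeded shuffle; no minimum spacing between rare stimuli
is enforced, since no such constraint is part of the design. All seeds
derive hierarchically (master → participant → session) from one master
seed, so any session regenerates in isolation and whole studies are
byte-reproducible.

What the generator does **not** emulate: biophysical volume conduction
(the topography is a layout-distance Gaussian, not a lead field),
eye-blink/EMG artifacts, stimulus-timing jitter, spatially correlated
noise, or latency variability of the P300. Passing tests on synthetic
data therefore demonstrate the correctness and sensitivity of the
*analysis*, not expected accuracy levels on real recordings.

## Preprocessing

`preprocess_session()` applies, in order:

1. **Startle removal** — the first 5 trials of each session are
   dropped.
2. **Band-pass** — Butterworth 0.1–8 Hz of design order 2 on the
   continuous record, one causal forward pass per channel. A causal
   filter is what an online BCI would run; it delays the P300 peak by
   ≈ 26 ms, which stays within one downsampled sample (31.25 ms).
   Zero-phase forward-backward filtering is available via
   `pipeline_config(zero_phase = TRUE)`. "Order 2" is read as the
   band-pass *design* order (4 poles in total); the 2-pole reading is a
   config away (`filter_order = 1`).
3. **Epoching** — the half-open window [−100, +900) ms gives exactly
   256 samples at 256 Hz and contains the −100–0 ms baseline. Because
   100 ms is 25.6 samples, window edges round to the nearest sample
   (the first sample sits at −101.6 ms); the epoch *length* is exact.
4. **Baseline correction** — per trial and channel, the mean over
   [−100, 0) ms is subtracted.
5. **Decimation** — every 8th sample is kept (256 → 32 Hz). No extra
   anti-alias filter is applied by default: the band-pass has already
   confined the signal to 8 Hz, inside the new 16-Hz Nyquist limit;
   `anti_alias = TRUE` adds a protective zero-phase low-pass anyway.
6. **Channel selection and vectorization** — channels restricted to
   all 64, the 47-channel central/parietal/occipital region of
   interest, or Cz alone, then concatenated channel-major into one
   feature row per trial (64 × 32 = 2048 features). In the 2-Target
   design the frequent 60-dB trials are excluded, leaving a balanced
   target-vs-nontarget problem.

## ERP statistics

Participant-level condition averages are computed from the full-rate,
baseline-corrected epochs. For the significance map, each average is
cut into 20-ms blocks (samples assigned by timestamp, so blocks
alternate between 5 and 6 samples; 50 blocks per epoch) and a paired
two-sided Wilcoxon signed-rank test compares target vs nontarget block
amplitudes across participants, per channel × block, at α = 0.05 with
no multiple-comparison correction (an optional `p.adjust` method is
off by default, matching the analysis convention of the paradigm).

The signed-rank kernel drops zero differences, tie-averages ranks of
|d|, and reports `W⁺`. For n ≤ 25 the p-value is exact: the null
distribution of W⁺ over all 2ⁿ sign assignments is obtained by
subset-sum convolution over the doubled (integer) ranks, and the
two-sided p is `P(|W⁺ − μ| ≥ |w − μ|)` with μ = S/2 — identical to full
enumeration, which the tests verify literally. Above n = 25 a normal
approximation with tie-corrected variance Σr²/4 is used. The Friedman
test reports the tie-corrected Q; for small tables (k ≤ 4, n ≤ 12 rows)
its p-value is likewise exact, by convolving the per-row rank
permutations over column-sum states (the tie-correction factor is
permutation-invariant, so `T = Σ(R_j − R̄)²` orders outcomes
identically), with the χ²(k−1) approximation otherwise.

The "peak amplitude" summary is the maximum of the participant's
target average at Cz within 300–500 ms — a window bracketing the
nominal 400-ms peak, since a peak-picking convention has to be fixed
somewhere.

## Classification

Binary target-vs-nontarget classification uses a linear soft-margin
hinge-loss SVM: `min_w ½‖w‖² + C Σ max(0, 1 − y_i w·x_i)`. The solver
is a dual coordinate-descent implementation (random permutation
sweeps, intercept as an appended constant feature). Inside nested CV
the same dual problem is solved on a precomputed linear Gram matrix —
one matrix per dataset serves the entire cost grid and all folds,
which matters because n ≪ d (≈ 500 trials × 2048 features). Tests
cross-check predictions against an independent SVM implementation
(libsvm via e1071).

Nested cross-validation is stratified and seeded: 5 outer folds
estimate accuracy; within each outer training set, 4 inner folds score
every cost in the grid 10⁻⁶ … 10³ (10 decades) by mean inner balanced
accuracy, ties broken toward the smallest C (strongest
regularization). The winning C is refit on the outer training set, and
the reported figure is the mean outer-fold *balanced accuracy* (mean
of per-class recalls — equal to plain accuracy for the balanced
2-Target problem, and the appropriate metric for the 4:1 imbalanced
1-Target problem).

**Trial averaging** raises SNR before classification: within each
class, trials are shuffled under a seed and partitioned into disjoint
groups of k (1–5); each group averages into one exemplar, remainders
are discarded. Averaging happens *before* the outer split, so every
raw trial contributes to exactly one exemplar and no trial leaks
between training and test folds. (Whether averaging should sit inside
or outside the CV loop is genuinely open; outside-with-disjoint-groups
is the leakage-free choice.)

## Reporting

`aggregate_table()` appends Average and SD footers to the
participants × k accuracy matrix. The SD is the *population* standard
deviation (divisor N): recomputing the published 2-Target table
verifies this convention (k = 1 column: mean 0.695, SD 0.051 with
divisor 10; divisor 9 would give 0.054). `halfsession_delta()` reports
`(mean first − mean latter) × 100` percentage points.
`wolpaw_itr()` implements the standard bits-per-selection form
`log₂N + P·log₂P + (1−P)·log₂((1−P)/(N−1))` with the P = 1 and
P = 1/N limits handled analytically; the selection rate is a free
parameter (default 60/min from the 1-s trial period), since a bits/min
figure is only meaningful relative to an assumed pacing.

## Numerical and design notes

* EDF I/O is a minimal 16-bit EDF reader/writer (one signal per
  channel, 1-s records, physical units µV, per-channel scaling from
  the data range); round-trips are exact up to the 16-bit
  quantization step. Events travel as plain TSV. Stimulus onsets are
  0-based sample indices and are taken as exact; hardware buffering
  jitter is not modelled.
* Degenerate inputs: all-zero difference vectors give p = 1 with a
  warning; constant Friedman rows give Q = 0; single-class truth makes
  balanced accuracy an error rather than a silent 0.5; unstable filter
  designs and out-of-bounds epoch windows raise errors naming the
  offending quantity.
* Problem sizes in the test suite are chosen to keep the full run in
  minutes on one CPU: the headline simulated-study checks use the full
  default study (10 participants × 20 sessions) for decodability and
  trial averaging, and scaled-down studies (4–5 participants, 8
  sessions) for the amplitude-sweep, chance-calibration and
  habituation checks; the null calibration of the significance map
  uses 20 independent single-session studies of 30 trials. Scaling
  down changes none of the tested properties, only their statistical
  resolution.
* Published per-participant accuracy tables of the original study of
  this paradigm ship as plain text in `extdata` and back the
  aggregation checks; the whole-study Friedman statistic printed there
  is not recomputable from the rounded per-participant cells and is
  therefore not a target.

## Known limitations

Synthetic accuracies are not calibrated to any real dataset; the
generator's SNR is a modelling choice. The topography model cannot
produce realistic spatial correlation of noise, so multichannel
accuracies are optimistic relative to Cz-only ones. The exact Friedman
path is limited to small tables; larger designs fall back to the
χ² approximation. EDF support covers the continuous-recording subset
of the format (no annotation channels, no discontinuous records).
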