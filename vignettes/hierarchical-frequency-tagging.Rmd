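---
title: "Hierarchical frequency tagging of concurrent speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical frequency tagging of concurrent speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hftag)
```

# The paradigm

In a dichotic-listening experiment a listener attends to natural speech in
one ear while the other ear receives a task-irrelevant stream of isochronous
250 ms syllables (4 Hz). In the **Structured** condition the syllable order
forms words (2 Hz), phrases (1 Hz) and sentences (0.5 Hz); in the
**Non-Structured** condition the same syllables appear in random order. The
two streams are therefore acoustically matched item-by-item and differ only
in syllable order. If the neural response shows spectral peaks at the rates
of higher linguistic units for the Structured stream, linguistic structure
in the *task-irrelevant* input is being tracked.

`hftag` implements the full analysis chain for this design — stimulus
construction, spectral phase statistics, permutation inference,
speech-tracking (TRF) estimation and behavioral scoring — together with a
simulator that generates multi-participant recordings with known injected
effects, so every statistical claim in the chain can be checked against
ground truth.

# Stimulus construction

## Syllable tokens

Real recorded syllables are replaced by synthetic tokens that keep exactly
the properties the analysis relies on:

* duration exactly 250 ms at the working audio rate (1000 Hz by default, so
  a token is exactly 250 samples);
* a monotone fade to zero over the final 25 ms (the counterpart of fading a
  truncated recording to avoid clicks);
* root-mean-square intensity equated across the bank to within 1e-6
  relative;
* pairwise distinct amplitude contours (pairwise correlation < 0.99).

Each token is band-limited Gaussian noise (center frequency log-uniform in
0.1–0.4 of the Nyquist, bandwidth one third of the center) under a smooth
gamma-shaped amplitude contour with a token-specific log-normal
perturbation (SD 0.30 of log-amplitude, ~25 ms correlation length) and a
token-specific jitter of the contour peak time (±15% log-uniform). Vocalic
energy dies out by ~220 ms, mirroring the silence padding of the original
recordings (mean token duration ~244 ms) and deepening the 4 Hz envelope
modulation.

The bank is split into two phonotactic classes: **onset-like** tokens with
an early contour peak (50 ms) and **coda-like** tokens with a later peak
(70 ms, more gradual rise). These numbers were chosen once, by a
grid search over token-synthesis parameters, so that three stimulus-level
facts hold simultaneously for generated sequences of a minute or more:
the 4 Hz bin exceeds its four flanking bins by at least a factor of 10 in
both conditions; Structured sequences show a clear 2 Hz local peak and
Non-Structured sequences none; and no local peak appears at 1 or 0.5 Hz in
either condition.

## The word-rate acoustic confound

Structured sentences come from a fixed inventory in which word-initial
slots (positions 1, 3, 5, 7 of each 8-syllable sentence) hold onset-class
tokens and word-final slots hold coda-class tokens — the synthetic
counterpart of the natural fact that different syllable subsets occur
word-initially versus word-finally. Because the envelope statistics then
alternate at the word rate, a 2 Hz component appears in the modulation
spectrum of Structured sequences *without any explicit 2 Hz modulation
being injected*; the Non-Structured condition uses the same bank in random
order and shows no such peak.

The inventory is **position-balanced**: every same-parity position uses a
permutation of the same token multiset across the inventory's sentences.
Averaged over the inventory the envelope is therefore exactly periodic at
the word rate, and carries no phrase- (1 Hz) or sentence-rate (0.5 Hz)
acoustic energy — which is what makes the neural comparisons at those
frequencies experimentally meaningful.

## Modulation spectrum

The stimulus spectral procedure deliberately mirrors the neural one:
RMS envelope (10 ms centered sliding window, reflect padding), 8 s
non-overlapping segments from the sequence start (dropping a 3 s onset
ramp when one was applied), un-tapered FFT per segment, magnitudes
averaged across segments. Segments are assumed non-overlapping; the
frequency grid is the FFT grid of an 8 s window, 0.125 Hz.

# The simulated neural world

Each trial of `simulate_trial()` is the sum of four components, all at a
neural sample rate of 200 Hz:

1. **Evoked syllable response** (both conditions, all channels): a fixed
   biphasic kernel of 150 ms support convolved with the 4 Hz syllable-onset
   impulse train, scaled by `syllable_response_amp` (default 0.5).
2. **Phrase-level tracking** (Structured only, `phrase_channels` only): a
   1 Hz sinusoid with amplitude `phrase_response_amp` (default 0.022) whose
   phase is fixed within a participant (drawn uniformly per participant) —
   the analysis only assumes segment-onset phase consistency, so a
   sinusoid stands in for any biophysical parsing model.
3. **Speech tracking**: a true TRF (Gaussian peaks at +80 ms and −140 ms,
   auditory channels at full gain, others at half) convolved with the
   attended-speech envelope. Kernels are normalized so that the response to
   a typical envelope has unit SD; `trf_amp` (default 0.15) is therefore
   the speech-tracking SNR against the unit-SD background noise. In the
   Structured condition an additional smooth bump spanning 70–180 ms is
   added on `trf_effect_channels`, normalized the same way and scaled by
   `trf_effect_amp` (default 0.05).
4. **1/f background noise**: FFT-synthesized noise with power spectrum
   `f^-noise_exponent` (default exponent 1), unit SD, independent across
   channels.

The attended narrative is simulated as smoothed positive noise (Gaussian
noise low-passed at 8 Hz, shifted positive) — the real narratives are out
of scope and the analysis uses only their envelope.

Channels carry abstract region labels (left/right × auditory, inferior
frontal, posterior parietal, occipital); no source modelling is attempted.
The default `phrase_channels` are the left inferior-frontal and
posterior-parietal groups, the published localization of the phrase-level
response; the TRF condition effect sits on the left inferior-frontal group.

## Calibration of the injected amplitudes

The published work reports effect sizes rather than SNRs, so the amplitude
defaults were tuned once, by simulation at the published scale
(29 participants, 15 trials/condition, 44 s trials), to reproduce the
reported effect-size regime, and then frozen:

* `phrase_response_amp = 0.022` puts the within-condition 1 Hz
  peak-versus-neighbors effect at Cohen's d ≈ 0.6 (reported: d = 0.6) and
  the between-condition 1 Hz comparison near d ≈ 0.5 (reported: d = 0.57);
* the 4 Hz syllable response at `syllable_response_amp = 0.5` gives d ≫ 1.5
  (reported: d > 1.5);
* `trf_amp = 0.15` yields leave-one-out predictive power r ≈ 0.12
  (reported: r = 0.1).

These calibrations describe the simulator's stated world; they are not
claims about the original recordings.

# Spectral statistics

Recordings are segmented into 8 s epochs starting at the first syllable
onset at or after the 3 s exclusion window (the ramped trial start is never
analyzed). With the default exclusion the segment start falls at 3.0 s —
on the syllable and phrase grid, though not on the sentence grid; since
segments step by whole sentences, every segment shares the same offset
within the sentence cycle, and phase *coherence* at every tag rate is
unaffected (the Rayleigh statistic is invariant to a common phase offset).

For every channel and frequency bin (0.125–15 Hz in 0.125 Hz steps — the
exact FFT grid of an 8 s window; a nominal 0.1 Hz start is not realizable
on this grid), the phase of each segment's un-tapered FFT is extracted and
the **Rayleigh z** computed: with `m` segments and mean resultant length
`R`, `z = m * R^2`. Its analytics anchor the tests: `z = m` under perfect
phase locking, `E[z] ≈ 1` under uniform phases, and `z` is invariant to
per-segment amplitude scaling. No taper is used because all tag rates fall
exactly on bins; a taper would leak power across the 0.125 Hz grid.

The scalp-level statistic averages z across channels *before* any group
test (avoiding per-channel multiple comparisons). A frequency of interest
(4, 2, 1 or 0.5 Hz) is tested by a paired t-test of z at the FOI against
the mean of two flanking bins per side, two-sided within condition (the
direction of a within-condition peak is not logically constrained);
between-condition comparisons are one-sided (Structured > Non-Structured,
the a-priori prediction).

# Permutation inference

All permutation p-values use the add-one rule
`p = (1 + #{null ≥ observed}) / (1 + n_perm)` with ties counted as
"≥ observed" (conservative), so `p ≥ 1/(n_perm + 1)`.

* **Condition comparison**: condition labels are switched in a random
  subset of exactly `floor(n/2)` participants per permutation — the
  literal reading of the published scheme. An independent-Bernoulli
  variant (the FieldTrip convention) is exposed via `scheme = "bernoulli"`.
  Empirically both control type-I error at α = 0.05 (the acceptance suite
  verifies the calibration over 400 null replicates).
* **ROI global statistic**: per-ROI paired t-tests at an uncorrected
  threshold (p < 0.05, two-sided); the *signed* sum of suprathreshold
  t-values is the global statistic (the prediction is directional; a
  sum-of-|t| variant is exposed). The half-swap null corrects for multiple
  comparisons across the ROIs of one hemisphere; hemispheres are tested
  separately. ROI values are channel means within each labeled group.
* **Spatio-temporal cluster permutation** for TRF comparisons: first-level
  paired t at every (unit, time) point, two-sided threshold p < 0.05;
  suprathreshold points cluster by spatial adjacency within a time bin and
  temporal adjacency within a unit, positive and negative points
  separately; cluster mass is the sum of t; the null is the maximum
  absolute cluster mass under per-participant sign flips. Units without
  spatial neighbors are permitted (with a warning) and cluster along time
  only. The ROI-level TRF variant first averages kernels in consecutive
  20 ms windows inside 70–180 ms; a trailing window that does not fit is
  dropped, leaving 5 full windows at the defaults.

# Temporal response functions

The TRF is estimated by normalized reverse correlation over a −50…400 ms
lag range: the kernel solves the pooled lag-domain normal equations, i.e.
the stimulus–response cross-covariance divided by the stimulus
autocovariance. Two hyperparameters, named after the original toolkit's
controls, are given concrete, testable definitions:

* **tolerance** ∈ (0, 1]: the fraction of autocovariance eigenvalue mass
  retained when pseudo-inverting; trailing eigencomponents beyond the mass
  cutoff are discarded (tolerance 1 keeps everything above numerical
  rank). This is the stabilizer for smooth, ill-conditioned stimuli.
* **sparseness** ≥ 0: a jackknife-stability threshold; kernel coefficients
  whose |jackknife mean| / jackknife SE across leave-one-trial-out
  re-estimates falls below the threshold are zeroed.

Both are selected by leave-one-trial-out cross-validation on predictive
power: the kernel estimated from N−1 trials predicts the held-out trial,
and the score is the Pearson correlation between prediction and recording,
averaged over folds and channels, with one lag-range worth of samples
discarded at each trial edge (convolution edge effects). In the pipeline
the envelope feature is the same broadband RMS envelope the stimulus
module produces, z-scored per trial (making predictive power scale-free),
and hyperparameters are selected once on the first participant's trials
collapsed across conditions and reused everywhere — the analysis-level
counterpart of selecting on pooled scalp data. Predictive power is
evaluated against a null of mismatched stimulus–response pairings
(derangements, so no trial keeps its own response), re-estimating and
re-scoring per permutation.

A band-limited stimulus identifies the kernel only inside its own band:
with the 8 Hz-low-passed synthetic envelope, sharp kernel features blur
and truncated inversion produces oscillatory side-lobes outside an
injected difference window. The cluster comparison therefore anchors on
the *top* cluster (which covers the injected window on the injected
channels); smaller significant side-lobe clusters on the same channels are
an honest property of regularized deconvolution, not a test failure.

# Behavioral analysis

Accuracy is the mean correct answer across four 3-alternative questions
per trial; chance is exactly 1/3 (0.33 is display rounding). The group is
tested against chance (one-sample t), between conditions (paired t), and
by a median split on the channel-averaged 1 Hz ITPC in the Structured
condition (two-sample two-tailed t on Structured accuracy and on the
condition difference; with an odd number of participants the median
participant joins the lower group, giving 15/14 at n = 29). The simulator
draws participant accuracies from N(0.715, 0.15²) clipped to [1/3, 1], the
published group moments.

# The end-to-end pipeline

`run_experiment()` streams one participant at a time (simulate → segment →
ITPC → TRF), then runs the group statistics, writing every table as TSV
with the master seed recorded in every row. One master seed derives all
stage seeds through a fixed affine map (`derive_seed()`), so a run is
bit-reproducible from its `run_config` alone; `write_run_config()` /
`read_run_config()` round-trip the configuration as plain text, and
`validate_report()` checks every table against the schema shipped in
`inst/extdata/report-schema.txt`. Any stage error aborts with the stage
name; tables already written are preserved.

`make_fixtures("tiny")` (6 participants, 4 trials/condition, 12 s trials,
200 permutations) exercises the full chain in seconds and is the test
fixture; `make_fixtures("default")` is the experiment at its published
scale (29 participants, 15 trials/condition, 44 s trials, 1000
permutations) and completes in under 3 minutes on one CPU. The TRF
predictive-power null runs on one representative participant (the first) —
re-estimating TRFs 1000× for every participant would dominate the budget
without changing what the check establishes.

```{r tiny-run}
report <- run_experiment(make_fixtures("tiny", seed = 1))
report$foi_tests[report$foi_tests$foi_hz %in% c(4, 1), ]
```

# What a green test establishes — and what it does not

The simulator reproduces the *statistical structure* the analysis assumes:
isochronous tagged stimuli, phase-locked responses confined to channel
groups, a linear speech-tracking response, 1/f noise, per-participant
gain and phase variability. It does not emulate real acoustics (no
phonology or prosody), sensor physics, artifacts (no ICA is needed or
implemented), anatomical source geometry, attention switching, or
correlations between behavior and neural responses (behavior is simulated
independently — the median-split analysis is exercised under its null).
Green tests therefore establish that the analysis chain measures what it
claims to measure on data with known ground truth at the published effect
sizes — not that the published biological claims are reproduced from real
recordings, which are out of scope.

Other numerical choices, in brief: the neural sample rate is 200 Hz so the
250 ms syllable grid, 20 ms windows and the 70 ms window edge all fall on
whole samples (a 250 Hz rate would alias the 4 Hz onset grid across
samples and inject a spurious phase-locked 2 Hz component the original
data do not contain); degenerate t-statistics follow the conventions
t(0/0) = 0 and t(c/0) = sign(c)·Inf; cluster masses are sorted by
decreasing magnitude; and all randomness flows from explicit integer
seeds kept below 2^31.
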