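---
title: "Methods: speech tracking and alpha power under noise-vocoded speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech tracking and alpha power under noise-vocoded speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechcoh)
```

This vignette documents the models, estimators, parameter choices and
numerical conventions of the `speechcoh` pipeline, and what the
synthetic-data generator can and cannot tell you about real recordings.

## 1. The scientific setting

Listening to spectrally degraded speech changes two things in cortical
recordings: the degree to which low-frequency activity synchronizes with
the slow amplitude envelope of the speech signal (*speech tracking*,
quantified as 1–7 Hz envelope–brain coherence), and induced alpha-band
power (8–12 Hz), often read as an index of neural activation or listening
engagement. The pipeline quantifies both across a ladder of noise-vocoding
levels (original speech, then 7-, 5-, 3-, 2-, 1-channel vocoding),
tests condition effects with cluster-corrected permutation statistics,
characterizes the shape of each measure across levels with mixed models,
and asks whether behavioral intelligibility is better predicted by the
two neural measures combined — as the ratio Tracking/Activation — than by
either alone.

## 2. Vocoder

`vocode()` implements classic noise vocoding:

1. `design_cochlear_bands(n, 200, 7000)` places `n + 1` band edges at
   equal distances along the basilar membrane using the Greenwood
   frequency–position map `F = A(10^(a·x) − k)` with the human constants
   `A = 165.4`, `a = 2.1`, `k = 0.88`. The first and last edges are
   pinned to 200 and 7,000 Hz exactly.
2. Each band is extracted with a 4th-order Butterworth band-pass applied
   **zero-phase** (forward–reverse, `signal::filtfilt`), so that no
   group-delay misalignment accumulates between bands. Zero-phase
   filtering doubles the effective magnitude order; we accept that, as
   the same filters are used for analysis and for the RMS reference.
3. The band envelope is half-wave rectification followed by a 4th-order
   zero-phase Butterworth low-pass at 250 Hz.
4. The envelope is normalized by its RMS (any normalization cancels in
   step 6, which is why the convention is safe), then multiplied with an
   independent, seeded white-noise carrier.
5. The modulated carrier is filtered back into the band.
6. The synthesized band is scaled so its RMS equals the RMS of the
   *original* signal filtered in the same band; the output is the sum of
   bands.

**Band-RMS accounting.** The per-band RMS match is exact (to rounding)
for the synthesis components, which `vocode(..., return_bands = TRUE)`
exposes. Measuring band RMS by *re-filtering the summed output* instead
picks up cross-band leakage through the Butterworth skirts plus
double-filtering attenuation — about 4% for adjacent bands. This is a
property of any non-ideal filterbank, so invariants (including
idempotence of vocoding with respect to band RMS) are stated and tested
on the synthesis components.

**Numerical note.** At audio rates the lowest bands sit at very small
normalized frequencies, where transfer-function-form IIR filters amplify
rounding noise in a scale-dependent way. All envelope extraction
therefore filters at unit input scale and rescales afterwards, which
makes positive homogeneity (scaling the input by c scales envelopes by c)
exact by construction.

## 3. Broadband speech envelope

`cochlear_envelope()` builds the envelope used for coherence: nine bands
spanning 100–10,000 Hz, equidistant on the same Greenwood map, 4th-order
zero-phase Butterworth band-passes, per-band magnitudes of the Hilbert
transform (computed by exact-length FFT), and an unweighted mean across
bands. The audio rate must exceed 20 kHz so the top band stays below
Nyquist; inputs are rejected (not silently resampled) otherwise —
resampling policy belongs to the caller.

`resample_envelope()` brings the envelope to the neural rate (150 Hz)
with polyphase anti-aliased resampling. The signal is edge-padded before
filtering so the FIR startup transient falls outside the data, the
output is trimmed to preserve duration within one sample, and small
negative ringing is clipped at zero (envelopes are nonnegative by
definition). The anti-aliasing FIR has ~1e-4 passband ripple; constants
are preserved at that accuracy.

The envelope is *not* explicitly aligned to the neural time axis beyond
sharing the rate and epoch grid; coherence magnitude is invariant to a
fixed lag, so alignment conventions do not affect the measures.

## 4. Spectral estimation

Recordings are cut into non-overlapping 2-s epochs (`segment_trials()`;
a trailing remainder is dropped) and, when conditions differ in epoch
count, subsampled to the smallest count with a seeded uniform draw
(`equalize_epoch_counts()`) — coherence is biased by the number of
averaged segments, so unequal counts would confound condition contrasts.

`dpss_tapers()` computes discrete prolate spheroidal sequences from the
standard symmetric tridiagonal commuting matrix (dense eigendecomposition;
N = 300 is small). For 2-s epochs and 3 Hz half-bandwidth this yields
the conventional K = 2TW − 1 = 11 tapers; tapers are orthonormal and the
leading taper concentrates > 99.9% of its energy within ±3 Hz. Unit
taper weights are used (no eigenvalue weighting), matching common
practice for these bandwidths.

`mtm_cross_spectra()` evaluates tapered FFTs on an integer-Hz grid: the
FFT length is the smallest multiple of the sampling rate covering the
epoch (300 samples at 150 Hz gives 0.5 Hz bins; every other bin is an
integer frequency), and bins 1–25 Hz are retained. Auto- and
cross-spectra are summed over tapers and trials; `coherence()` normalizes
to

C(ch, f) = |Σ S_xy|² / (Σ S_xx · Σ S_yy),

which is bounded in [0, 1], equals 1 identically for a single
trial-taper product (rank-1 degeneracy), and has expectation ≈ 1/M for
independent signals averaged over M = trials × tapers products. Zero
auto-spectrum bins yield coherence 0 with a warning rather than NaN.
`power_spectra()`/`alpha_power()` return the trial- and taper-averaged
auto-spectra and their 8–12 Hz band mean. Band averages are unweighted
means over inclusive bins, so 1–7 Hz averages exactly seven bins.

A caveat worth knowing: for a *nonnegative* envelope the 1–2 Hz bins
contain leakage of the large DC mean through the ±3 Hz taper window, so
envelope "power" there does not reflect syllabic modulation; coupling
effects concentrate at the syllable-rate bins (3–7 Hz).

## 5. Cluster-corrected permutation ANOVA

Per (channel, frequency) cell, a one-way within-subjects ANOVA across
conditions gives F = MS_condition / MS_condition×subject with
df = (k − 1, (n − 1)(k − 1)). Multiple comparisons are controlled by the
max-cluster Monte Carlo test:

- **Cluster-forming threshold:** the parametric F critical value at
  `cluster_alpha = 0.05` for (df1, df2). The threshold choice affects
  sensitivity, not validity.
- **Connectivity:** spatial neighbors at the same frequency, plus the
  same channel at adjacent 1 Hz bins (`freq_adjacent = TRUE` by
  default). Spatial-only clustering is available by switching that flag.
- **Null distribution:** condition labels are permuted independently
  within each subject (the exchangeability implied by the
  within-subjects null); the maximum summed-F cluster statistic of each
  of `n_perm` permutations forms the null.
- **P-values:** `(1 + #{null ≥ observed}) / (1 + n_perm)`, never exactly
  zero; clusters are significant below `alpha = 0.05`.

Results are bit-reproducible given data, seed and `n_perm`. Post hoc
dependent-samples t tests between all condition pairs (on
cluster-averaged values) are corrected with Benjamini–Hochberg at
q = 0.05.

## 6. Mixed models

All mixed models are random-intercept models fit by **maximum
likelihood** (not REML), because fixed-effect structures are compared by
likelihood-ratio tests. The vocoding level enters as an ordinal code
1 (clearest) … 6 (1-channel), centered before squaring so the linear and
quadratic terms are uncorrelated; the coding is a modeling convention,
not data. `lrt()` reports χ² = 2Δlog-likelihood with df equal to the
parameter difference.

For the intelligibility models, each subject's tracking and alpha values
are first normalized by that subject's value in the clear (nonvocoded)
condition (`normalize_by_clear()`; clear rows are then dropped, and
subjects with near-zero clear values are excluded with a warning). Three
models of the per-subject hit rate across the five vocoded conditions —
predictor T/A (combined), T, or A — are each tested against the
intercept-only null by LRT. The combined-vs-single comparisons are
**non-nested**, so they are reported as log-likelihood differences and
AIC, not as an LRT; equal parameter counts make the two orderings agree.
Hit rates are modeled on the proportion scale, matching how such results
are usually displayed; a logit link would be a reasonable alternative for
rates near ceiling.

Group-level predicted curves per level are the fixed-effect design times
the coefficients (random intercepts have mean zero), tabulated for both
the linear and quadratic fits in the analysis report.

## 7. The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are the
generator's definition of the experiment, chosen once:

- **Conditions:** original, 7-, 5-, 3-, 2-, 1-channel vocoding, in that
  (clearest-first) order; 12 subjects; 20 2-s epochs per subject and
  condition at 150 Hz. These sizes keep a full simulated study around
  seconds of compute while leaving every effect detectable; they are
  deliberately smaller than a real MEG study (~200 epochs/condition).
- **Coupling profile** κ = (0.5, 0.9, 1.2, 1.0, 0.75, 0.5): an
  inverted U peaking at 5-channel vocoding and equal-lowest for clear
  and 1-channel speech — the qualitative tracking profile the pipeline
  is designed to detect. Envelope-coupled channels are a 6-channel
  "temporal" patch on an 8×8 grid with 4-neighborhood adjacency.
- **Alpha profile** α = (1.0, 0.8, 0.6, 0.6, 0.6, 0.6): monotone decline
  reaching a floor from the 5-channel level onward, in a disjoint
  6-channel "parietal" patch, realized as a 10 Hz sinusoid with a fresh
  uniform phase per trial and channel.
- **Behavior:** hits ~ Binomial(20, p_c) with p descending from ~0.99 to
  the 50% 2AFC chance level as a logistic in log2(channel count)
  (`default_hit_profile()`; the original condition is treated as
  20 channels, i.e. spectrally intact for this task). The anchor values
  approximate typical degraded-speech word-recognition performance.
- **Noise:** 1/f (exponent 1) background noise of unit SD in every
  channel; envelope-to-brain lag 100 ms (inert for coherence magnitude).
- **Envelopes:** syllabic burst trains — gamma-jittered inter-burst
  intervals around 1/4.3 s (CV 0.2), gamma-shaped bursts (~60 ms),
  lognormal amplitudes, and a slow multiplicative modulation — giving a
  spectral peak in 3–6 Hz. `gen_speech_audio()` additionally modulates
  three cochlear-spaced noise subbands with partly shared envelopes
  (pairwise correlation ~0.5), so that coarse vocoding genuinely
  discards envelope detail as it does for natural speech.

`make_measure_table()` draws the same study at the summary level
(per-subject tracking, alpha, hit rate without time series), for fast
model-recovery studies: tracking means follow 0.015 + 0.1 κ² (a
coherence-scale image of the coupling profile), alpha means follow α.
Residual tracking noise is scaled to the programmed curvature
(SD = 0.3 |quadratic coefficient|) and alpha residual noise is 0.05 in
α's units, with subject intercept SDs of 0.02 and 0.1 respectively.
`gen_intelligibility_table()` generates behavior from a chosen
ground-truth mechanism — linear in T/A (slope 0.05, intercept 0.45,
response noise 0.05, chosen so predictions stay inside [0, 1] and the
mechanism remains linear), linear in T alone, or constant — to test that
the model comparison recovers the generating mechanism and does not
overfit.

**What passing tests do and do not show.** The generator emulates the
*statistical structure* the analysis assumes: condition-locked coupling
and alpha profiles, 1/f noise, binomial behavior, exchangeable condition
labels under the null. It does not emulate sensor physics (no forward
model or field spread), artifacts (blinks, cardiac), non-stationarity,
perceptual learning across a session, or between-subject anatomical
variability. Recovery on synthetic data therefore validates the
estimators and their calibration — type-I error, power, shape selection —
not the neuroscientific claims themselves on real recordings.

## 8. Verification design and problem sizes

Every estimator is checked against an independent oracle: Greenwood
inversion against numeric root-finding; the rectified-sine envelope mean
against its analytic value A/π; DPSS concentration against the sinc
kernel quadratic form; the repeated-measures F against both `aov()` and
a hand-written sums-of-squares decomposition; BH against a brute-force
step-up; cluster components against `igraph`; coherence against its
exact degeneracies (self-coherence 1, single trial-taper 1) and its 1/M
independence floor by simulation.

The calibration studies run at sizes chosen to finish in minutes on one
CPU while keeping Monte Carlo error well below the decision margins:
family-wise error over 200 null datasets (12 subjects × 3 conditions ×
64 channels × 7 frequencies) at 500 permutations, judged against the
exact binomial 95% band around 0.05; planted-patch recovery over 50 runs
(20 subjects, 2 conditions, 10 trials, white background noise, coupling
calibrated per run by solving C = κ²P/(κ²P + 1) for a 0.15 band-mean
uplift) requiring a significant cluster with channel-Jaccard ≥ 0.3
against the planted patch; and model-selection rates over 50 seeds each
for the inverted-U, floor, null-linear and intelligibility scenarios.

## 9. Known limitations

- The vocoder's carrier is band-limited white noise; sine carriers and
  spectral rotation are out of scope.
- Coherence is the only tracking measure (no TRFs, mutual information,
  or inter-trial correlation).
- The cluster test assumes a complete subjects × conditions design; no
  imputation is attempted.
- Non-nested intelligibility model comparison relies on AIC/log-likelihood
  heuristics; a formal test (e.g. Vuong) is not provided.
- Data exchange is R-native (in-memory structures, CSV/JSON, RDS via the
  CLI); no HDF5 reader is provided, so externally stored epoch containers
  must be converted by the caller.
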