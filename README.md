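# speechcoh

Analysis pipeline for studying how spectral degradation of continuous
speech — noise vocoding — modulates two neural measures recorded during
listening: low-frequency (1–7 Hz) **speech–brain coherence** ("speech
tracking") and **alpha-band power** (8–12 Hz, an engagement/activation
proxy), and for predicting behavioral speech intelligibility from the two
measures combined.

It is aimed at auditory cognitive neuroscientists who work with
channel- or source-level M/EEG time series and continuous speech stimuli,
and at methodologists who want every stage of such a pipeline to be
verifiable against ground truth.

## What the pipeline computes

**Stimulus side.** An n-channel noise vocoder splits a waveform into
Butterworth analysis bands spanning 200–7,000 Hz at equal distances along
the basilar membrane (Greenwood map, F = A(10^{ax} − k) with the human
constants A = 165.4, a = 2.1, k = 0.88), extracts each band's envelope by
half-wave rectification and 250 Hz low-pass filtering, modulates a seeded
noise carrier, and RMS-matches each resynthesized band to the original.
The broadband *speech envelope* used for coherence is the across-band
mean of Hilbert magnitudes from a nine-band cochlear filterbank
(100–10,000 Hz), resampled to the 150 Hz neural rate.

**Neural side.** Recordings are cut into 2-s epochs and submitted to DPSS
multitaper spectral estimation (1–25 Hz in 1 Hz steps, 3 Hz smoothing,
K = 2TW − 1 = 11 tapers). Speech tracking is the trial- and
taper-averaged magnitude-squared coherence

C(ch, f) = |Σ S_xy|² / (Σ S_xx · Σ S_yy) ∈ [0, 1],

between each channel and the speech envelope; alpha power is the averaged
auto-spectrum in 8–12 Hz.

**Statistics.** Condition effects are tested per (channel, frequency)
cell with a one-way repeated-measures ANOVA,
F = MS_condition / MS_condition×subject, corrected for multiple
comparisons by a Monte Carlo max-cluster permutation test (condition
labels shuffled within subjects, default 5,000 permutations, clusters
formed over spatial neighbors and adjacent 1 Hz bins). Post hoc paired t
tests are Benjamini–Hochberg corrected. Measures are then modeled across
the six degradation levels (original, 7-, 5-, 3-, 2-, 1-channel) with
random-intercept mixed models, comparing `measure ~ level` against
`measure ~ level + level²` by likelihood-ratio test, and behavioral
intelligibility is modeled from the normalized neural measures:

Intelligibility = Tracking / Activation (combined model),

compared against tracking-only and activation-only models by
log-likelihood and AIC.

**Synthetic data.** Because the scientific claims concern estimator
behavior, a generator (`sim_config()`, `make_dataset()`) produces fully
synthetic studies with known ground truth: syllabic speech envelopes
(mean rate 4.3 Hz), an 8×8 sensor grid with a coupled "temporal" patch
(inverted-U coupling profile peaking at 5-channel vocoding), an alpha
"parietal" patch (declining profile with a floor from 5-channel onward),
1/f background noise, and binomial 2AFC behavior descending from ceiling
to the 50% chance level.

## Worked example

```r
library(speechcoh)

# 1. vocode a speech-like test signal and check envelope preservation
audio <- gen_speech_audio(duration_s = 10, rate = 22050, seed = 1)
voc7  <- vocode(audio, vocoder_config(n_channels = 7, seed = 2))
env0  <- resample_envelope(cochlear_envelope(audio), 150)
env7  <- resample_envelope(cochlear_envelope(voc7), 150)
cor(env0$values, env7$values)
#> envelope correlation, original vs 7-channel vocoded: r = 0.888

# 2. simulate a 12-subject study and run the full analysis
cfg <- pipeline_config(sim = sim_config(n_subjects = 12, n_trials = 20, seed = 7),
                       n_perm = 2000, seed = 7)
report <- run_full_analysis(cfg)
print(report)
#> Speech tracking cluster test:
#> <cluster_test_result> 8 cluster(s), threshold F(5,55) = 2.383, 2000 permutations
#>   stat = 2301.94, 32 cells, p = 0.0004998 *
#>   stat = 10.74, 3 cells, p = 0.6252
#>   ...
#> Alpha power cluster test:
#> <cluster_test_result> 4 cluster(s), threshold F(5,55) = 2.383, 2000 permutations
#>   stat = 21909.35, 35 cells, p = 0.0004998 *
#>   stat = 787.04, 17 cells, p = 0.0004998 *
#>   ...
#> Linear vs quadratic LRT p-values:
#>   hit_rate: chi2 = 0.059, p = 0.8088
#>   tracking: chi2 = 181.192, p = 2.662e-41
#>   alpha: chi2 = 158.081, p = 2.971e-36
```

Reading the output: the 7-channel vocoded stimulus has a nearly identical
broadband envelope to the original (r = 0.89) — by design, vocoding
degrades spectral detail while sparing the slow amplitude structure. The
tracking cluster test finds one significant spatio-spectral cluster
(32 cells, Monte Carlo p ≈ 0.0005) over the planted coupled patch, and
the alpha test finds the planted alpha patch. The quadratic level term is
decisively preferred for tracking (the inverted-U coupling profile) and
for alpha (decline to a floor), but not for the near-linear behavioral
profile — exactly the shapes the generator programmed.

A command-line wrapper for the main stages (`vocode`, `envelope`,
`simulate`, `run-all`) is installed at `inst/cli/speechcoh-cli.R`.

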