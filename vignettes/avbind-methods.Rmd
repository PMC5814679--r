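---
title: "Audio-visual binding in auditory cortex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audio-visual binding in auditory cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avbind)
```

## The scientific problem

When a listener faces two competing voices, a visual stimulus whose
luminance varies in time with the intensity of one voice can help bind that
voice into a single cross-modal object. `avbind` implements the full
analysis chain used to test this idea electrophysiologically in auditory
cortex: artificial-vowel streams with independent noisy amplitude
envelopes, a luminance-modulated visual stimulus that is temporally
coherent with one stream, spike-pattern decoding of which stream a neuron
"follows" in a mixture, discrimination of brief timbre deviants (a feature
orthogonal to the envelope that mediates binding), and phase-dissimilarity
analysis of the local field potential (LFP).

Because the original recordings are not publicly released, the package
pairs every analysis with a synthetic-electrophysiology generator that
encodes, as ground truth, exactly the response properties the analyses are
designed to detect. All statistical machinery can therefore be validated
end-to-end: null cases must stay null, and planted effects must be
recovered in the direction and location where they were planted.

## Stimuli

Two vowel streams are synthesized: A1 = [u] (formants 460, 1105, 2857,
4205 Hz, F0 = 195 Hz) and A2 = [a] (936, 1551, 2975, 4263 Hz, F0 =
175 Hz). Each stream is amplitude modulated by an independent noisy
low-pass envelope (7 Hz cut-off), and the visual stimulus is a full-field
luminance whose time course equals one stream's amplitude envelope.
Conditions combine one or both auditory streams with one visual stream
(A1V1, A1V2, ..., A12V1, A12V2) plus no-visual controls.

Numerical choices:

* **Envelope generator.** Gaussian white noise, zero-phase frequency-domain
  low-pass (unity gain to 0.8 x cut-off, raised-cosine roll-off reaching
  zero *at* the cut-off), min-max normalized to [0, 1]. Placing the
  roll-off below the cut-off makes the stop band exact, so the spectral
  invariant (no power above 7 Hz) holds by construction for every seed.
* **Vowel synthesis.** A flat harmonic comb at F0 whose harmonic amplitudes
  sample the magnitude response of a cascade of four two-pole resonators
  (bandwidths 80, 120, 160, 200 Hz, configurable). This is spectrally
  identical to filtering an impulse train through the resonators, but,
  unlike time-domain IIR filtering, it has no filter memory: a
  time-varying formant trajectory affects only the samples at which it
  differs, which is what makes the timbre-deviant contract (exact sample
  equality outside the deviant epoch) testable to the last bit.
* **Timbre deviants.** 200-ms epochs in which F1 and F2 follow a
  raised-cosine trajectory to the morph target ([u] to [eps], [a] to [i])
  and back, reaching the target at the epoch midpoint. Harmonic amplitudes
  are renormalized to constant instantaneous power, so the deviant is
  amplitude-neutral (RMS within a fraction of a percent) and carries no
  envelope cue; deviant onsets are free parameters
  (`default_deviants()` places two per stream at 0.8/1.9 s and 1.3/2.4 s).
* Audio rate 24414 Hz; trials are 3 s, the analysis window used throughout.

## The synthetic-electrophysiology generator

The generator is deliberately minimal: inhomogeneous Poisson spiking (1-ms
steps) with intensity

    baseline + g_A * sum_s c_s * w_s * env_s(t - latency) + g_V * w_V * env_V(t - latency)

where `w_s` is a per-trial multiplicative gain, Gaussian around 1. Three
coupling mechanisms carry the effects under study, all controlled by the
coherence-reliability parameter `kappa`:

1. **Reliability.** The gain noise of a stream that is temporally coherent
   with the luminance is divided by `1 + kappa`. Coherence thus increases
   the trial-to-trial reliability of the response without changing its
   mean — matching the observation that evoked rates do not differ between
   coherent and independent single-stream stimuli.
2. **Stream capture (mixtures only).** In dual-stream conditions the
   coherent stream's drive weight is `1 + delta` and the other stream's
   `1 - delta`, with `delta = 0.5 * kappa / (1 + kappa)`. Total drive is
   conserved because the two envelopes have equal means, and single-stream
   conditions are untouched, so the single-stream rate control still holds
   exactly. Without this channel, pilot simulations showed that a pure
   reliability effect moves dual-stream decoding only through accidental
   asymmetries in envelope energy: the visual-preference recovery required
   of the generator (a significant-VPI fraction that grows with `kappa`)
   was flat at the few-percent level, so reliability alone cannot generate
   the phenomenon the decoder must detect.
3. **Deviant enhancement.** Inside a deviant epoch the driving stream's
   envelope is scaled by `1 + deviant_gain * (1 + kappa)` when that stream
   is coherent with the luminance and `1 + deviant_gain` otherwise. In a
   200-ms, 10-ms-binned epoch, Poisson noise dominates the per-trial gain
   noise, so an explicit enhancement of the planted deviant response is
   the only way a coherent-versus-independent difference of useful size
   can arise.

Defaults (`unit_params()`): baseline 5 spikes/s, auditory gain 30 spikes/s
per unit envelope, latency 20 ms, `trial_noise_sd = 0.6` (single-trial
gain variability of cortical responses is large; smaller values make the
reliability channel invisible next to Poisson noise), 20 trials per
condition (the recorded repetitions ranged 14 to 34 with mean 20).

The LFP site model is `1/f` background noise plus an auditory evoked
component following the summed envelope, plus a band-limited oscillation
(default 8 to 15 Hz) whose phase is reset toward a fixed target at each
upward crossing of luminance 0.5. Two details matter:

* The reset replaces the oscillator phase by a von Mises draw whose
  concentration is chosen so the mean resultant length equals
  `reset_strength`; `reset_strength = 0` is a pure null.
* A phase slew is the only way a reset can leak into *power*: the
  instantaneous-frequency excursion during the transition produces a dip
  in band power that is time-locked to the trigger. The generator
  therefore jitters the slew onset (0 to 150 ms) and duration (150 to
  350 ms) per trial, and gives the oscillation a slowly varying random
  amplitude (0.5 to 1.5, low-passed noise, independent across trials).
  After these two measures the power statistics are identical across
  visual conditions while the phase distribution is not — the dissociation
  that the power-dissimilarity control is designed to verify.

## Spike-pattern decoding

Responses are binned from 0 to 3 s in 20-ms bins (150 bins; half-open
bins, a spike at the window end is excluded). The classifier assigns each
trial to the class with the nearest mean template in Euclidean distance,
excluding the held-out trial from its own class template (leave-one-out);
distance ties are broken uniformly at random under the caller's seed.

* **Unit classification.** Auditory axis: pooled A1V1+A1V2 versus
  A2V1+A2V2; visual axis: pooled A1V1+A2V1 versus A1V2+A2V2; a unit is
  auditory-discriminating, visual-discriminating, both, or none according
  to which axes beat their permutation null.
* **Dual-stream decoding.** Templates are the full-condition mean
  responses to the coherent single-stream stimuli (A1V1, A2V2) — or to
  auditory-only stimuli as a control — and every A12V1/A12V2 trial is
  labeled A1 or A2. No leave-one-out is needed because template and test
  conditions are disjoint. The **visual preference index** is the
  percentage of A12V1 trials labeled A1 minus the percentage of A12V2
  trials labeled A1, with percentages truncated to whole percents before
  subtraction (the printed convention; 19/23 prints as 82).
* **Permutation tests.** 1000 iterations; a response is significantly
  informative when the observed score exceeds the null's 95th percentile.
  Because decoding scores are discrete (multiples of one trial),
  exceedance ties carry real probability mass and the plain rule is
  conservative; ties are therefore broken by uniform random jitter far
  below the score granularity, making the test exactly calibrated (5%
  false positives at `alpha = 0.05` by construction). The default null
  permutes the observed labels (an exact scheme); resampling trials with
  replacement before relabeling is available as `scheme = "bootstrap"`,
  but is conservative for high-dimensional spike patterns because a
  duplicate of the held-out trial pulls its own class template closer.
  The VPI permutation shuffles the identities of the single-stream
  template trials and uses two-sided exceedance on |VPI|, computed on raw
  (untruncated) percentages so the null is not discretized by the printing
  convention.

## Timbre-deviant analysis

For each deviant, 200-ms epochs (10-ms bins, 20 bins) are extracted from
deviant-bearing trials and from the identical time window of the
otherwise-identical no-deviant stimulus; unequal trial counts are evened
by seeded subsampling of the larger set. The same leave-one-out classifier
discriminates deviant from no-deviant epochs; a deviant counts as
*detected* when the permutation test (95th-percentile rule) passes.
Deviants are decoded separately and then averaged — per unit the summary
reports the number detected (maximum 4, two per stream) and the mean score
over detected deviants, grouped by whether the deviant's stream was
temporally coherent with the visual stream.

## LFP phase and power dissimilarity

Each trial is decomposed with complex 7-cycle Morlet wavelets on a grid of
86 frequencies (2.5 to 45 Hz in 0.5-Hz steps; unit-energy wavelets,
Gaussian truncated at three temporal standard deviations). Samples within
half a wavelet support of either trace end are excluded from all time
averages, per frequency. Inter-trial phase coherence (ITPC) at each
time-frequency point is the modulus of the mean unit phasor across trials;
the within-stimulus ITPC profile averages this over the valid window.

The across-stimulus ITPC re-computes the same quantity over trials drawn
at random from two conditions that share the auditory stimulus but differ
in the visual one (N = the smaller trial count, averaged over 100 draws;
the draw count is a free parameter). The phase dissimilarity index (PDI)
is the within-minus-across difference per frequency: single-stream PDI
values are averaged over the two stimuli of each coherency grouping
(coherent: A1V1/A2V2; independent: A1V2/A2V1), and the dual-stream PDI
averages A12V1 and A12V2 against their mixed-draw null. Because the
compared conditions contain identical sounds, any positive PDI is
attributable to the visual stream.

Significance across recording sites uses a paired one-sided t test per
frequency at a Bonferroni-corrected level (0.05 divided by the number of
frequencies — 86 on the default grid; for a 43-frequency analysis the
corrected level prints as 0.0012), and a frequency counts only inside a
run of at least two adjacent significant bins. The PDI magnitude is the
sum of the mean PDI over significant frequencies.

The **power dissimilarity** control substitutes normalized single-trial
power time courses for unit phasors. The source analysis leaves the power
analogue unspecified; here consistency at each frequency is the mean
pairwise Pearson correlation of per-trial power time courses (each divided
by its in-window mean — correlation makes any per-trial scale choice
immaterial, but the normalization is kept explicit), within stimulus
versus across mixed draws. With phase-only resets this index stays null;
it turns positive only if the visual stream modulates band power
(available in the generator via `power_boost`, for positive controls).

Time decimation: coefficients below 45 Hz vary slowly, so the analysis
pipeline keeps every fourth sample of the 600-Hz coefficient time courses
before time averaging; this changes no statistic beyond numerical noise
and reduces memory and matrix sizes fourfold.

## What passing tests do and do not show

The generator emulates envelope-following units with Poisson variability,
coherence-dependent reliability and stream capture, deviant-evoked rate
perturbations, and luminance-locked phase (not power) resets — the minimal
structure the analyses assume. It deliberately omits cross-unit noise
correlations, laminar structure, non-Poisson spiking statistics, adaptation
within trials, and any biophysics. Green tests therefore certify that the
analysis chain is correct and calibrated (nulls stay null, planted effects
are recovered where planted), not that real auditory-cortex data would
show these effects.

## Problem sizes used by the validation suites

Chosen to exercise the statistics at the scale the analyses are meant for
while staying comfortable on a single CPU: null-calibration suites use 500
no-signal units with 14 trials per condition and 1000 permutation
iterations; parameter-recovery suites use a 100-unit population (40%
auditory, 10% visual, 50% undriven, `kappa = 1.5`, 20 trials) and 20
seeded LFP replicates of 8 sites each (14 trials, `reset_strength = 0.8`);
eight sites keep the Bonferroni-corrected paired t test (df = 7) powered at
the corrected level. A 7-cycle wavelet at frequency f has spectral
standard deviation f/7, and phase locking leaks up to about three spectral
sds beyond a band edge, so the "only inside the band" check treats only
frequencies further out than that as genuinely off-band.

## Known limitations

* The envelope-asymmetry of any given seed pair sets how strongly the
  stream-capture channel expresses in decoding; direction is robust,
  magnitude varies with the stimulus draw.
* The deviant epochs are decoded per deviant and averaged; pooling epochs
  before decoding (an alternative reading of the source procedure) is not
  implemented.
* ITPC edge exclusion leaves only ~0.3 s of valid window at 2.5 Hz in a
  3-s trial; the lowest frequencies of the default grid are accordingly
  noisy and materially constrained by trial length, as in the original
  design.
* The fixed 65 dB SPL level is metadata; no acoustic calibration is
  modelled.
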