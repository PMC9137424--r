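---
title: "Simulating face-mask degradation of audiovisual speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating face-mask degradation of audiovisual speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masksim)
```

`masksim` simulates the two ways a face mask degrades audiovisual speech —
high-frequency acoustic attenuation and occlusion of the talker's mouth —
and analyzes closed-set consonant identification data collected with such
stimuli. This vignette is the package's account of the underlying models,
the tunable parameters, the numerical choices, and what the synthetic
generators do and do not emulate.

## The acoustic model

A mask is characterized entirely by its *attenuation function* A(f): the
dB loss it imposes relative to the unmasked talker. We estimate it from a
paired recording (the same speech material with and without the mask):

1. Long-term magnitude spectra by Welch's averaged periodogram:
   512-sample Hamming-windowed segments with 256-sample overlap, averaged
   one-sided, reported as 10·log10 of mean power. At the working rate of
   44.1 kHz this gives 257 bins from 0 to 22.05 kHz, ~86 Hz apart.
2. A(f) = L_ref(f) − L_mask(f), clamped to ±30 dB. The clamp only
   matters in bins dominated by measurement noise, where the raw
   difference is meaningless; 30 dB is far above any realistic fabric or
   plastic-window loss.
3. A linear-phase FIR filter with magnitude 10^(−A(f)/20) is synthesized
   by frequency sampling (`signal::fir2`), default order 128, i.e. 129
   symmetric taps. Filtering keeps the input length and compensates the
   group delay of order/2 samples, so output and input are time-aligned.
   Zero attenuation yields the all-pass control applied to unmasked
   stimuli, keeping the processing chain identical across conditions.

Attenuation is summarized by the mean over 2–16 kHz (inclusive bin edges,
unweighted) and by the peak mean within standard one-third-octave bands
(nominal base-2 centers …3150, 4000…16000 Hz; exact edges
center·2^(±1/6); ties broken toward the lowest center).

Two conventions are worth stating. "Spectrum in dB" means power dB
(10·log10); since attenuation is a *difference* of spectra, power-dB and
amplitude-dB conventions give identical values. And "128-point FIR" is
read as filter order 128 (129 taps); an even order keeps the group delay
an integer.

### Numerical behavior and limits

The frequency-sampling design reproduces smooth profiles to within about
0.5 dB at order 128; the all-pass control is flat to well below 0.1 dB.
The estimator's main limitation is spectral leakage: with a Hamming
window (−42 dB sidelobes), bins where the reference spectrum sits more
than ~40 dB below its peak absorb leaked low-frequency power in *both*
channels, which compresses the measured attenuation there. For
speech-shaped material this starts to bite above ~12 kHz, where recovered
attenuation can read up to ~1 dB low; within 0.2–10 kHz, recovery of a
known profile from a 60-s pair is accurate to < 0.25 dB. This is a
property of the spectral instrument, not of the filters.

Base R's `convolve()` is avoided for filtering: its FFT length is the raw
signal length, which can contain a large prime factor and degrade to
quadratic cost. Long convolutions are done by FFT on a 2-3-5-smooth
padded length; short ones directly.

## Calibrated trials

Levels are *nominal*: a `calibration_map()` assigns a dB SPL value to a
full-scale digital RMS (default 0 dBFS ≡ 100 dB SPL, so the standard
70 dB SPL noise sits at −30 dBFS with generous headroom). Speech-shaped
noise is seeded Gaussian noise shaped by a frequency-sampling FIR built
on the reference spectrum; the shaping filter's order defaults to 1024 —
higher than the mask filters — because matching a speech spectrum down to
100 Hz needs finer low-frequency resolution than a 129-tap filter
provides. A 60-s realization matches the reference shape within ~1 dB
(tolerance 2 dB) over 0.1–10 kHz.

Trials are assembled as: a seeded contiguous excision from the 30-s
noise, scaled to the target SPL, with 20-ms raised-cosine onset/offset
ramps; the token scaled so its *speech-span* RMS sits `snr_db` above the
noise RMS, inserted at the timeline's speech onset (default 776 ms after
noise onset; the video reference point is 186 ms after noise onset with a
≥333 ms neutral-face lead). The speech-span annotation is authoritative
for both RMS equalization and SNR — silence padding never dilutes a
level. Mixing therefore realizes the requested SNR exactly by
construction; the tests verify it post hoc to 0.1 dB by component
subtraction. Clipping (|sample| > 1) is an error, not a warning.

## Visual occlusion

Landmark frames follow the package's canonical 66-point layout (17
lower-face perimeter, 10 brows, 4 nose bridge, 5 nostril base, 12 eyes,
18 lips), since the original detector's index order is not standardized.
The opaque mask is one polygon through the 17 perimeter points plus the
top nose-bridge point. The windowed ("communicator-style") mask adds a
rectangular hole: the axis-aligned bounding box of the 18 lip points
dilated on every side by `window_margin` × mouth width (default 0.2 — a
visually plausible cutout that always clears the lips; configurable). A
fully transparent mask draws nothing.

Rendering fills pixels whose centers fall strictly inside the region
(outer polygons minus holes) with pure white, no anti-aliasing — so
rendering is byte-exact idempotent and testable to the pixel. Occlusion
reports count landmarks inside the filled region per anatomical group;
boundary landmarks count as occluded for outer polygons (the perimeter
points sit on the mask edge) but a landmark strictly inside a hole is
visible.

## Scoring

The response set is 12 consonants in CV syllables with /i/; the
postalveolar fricative is serialized `"sh"`. Features are assigned
voicing 6/6, manner 5/5/2, place 4/5/3. Feature transmission is the
proportion of trials whose response shares the target's feature value —
*proportion-correct-by-feature*, matching the "feature transmission
accuracy" usage; Miller–Nicely information transfer is deliberately not
the primary statistic (it is a different quantity and would not match
reported accuracies). A correct response transmits every feature, so each
transmission is bounded below by accuracy; chance levels under a uniform
responder are 1/12, 0.5, 54/144 and 50/144.

Runs are pooled by summing counts per subject × condition before
computing proportions and RAU (the alternative — transforming per run and
averaging — gives a noisier, biased statistic at 36 trials/run);
incomplete cells are excluded by default. The RAU transform is the
standard linear-rescaled two-term arcsine: θ = asin√(X/(N+1)) +
asin√((X+1)/(N+1)), RAU = (146/π)θ − 23, which maps 18/36 to exactly 50
and satisfies RAU(X,N) + RAU(N−X,N) = 100.

## Inference

RAU scores are modeled with `lmerTest::lmer`: fixed factors (default
mask × modality × group), a random intercept per subject, REML fits,
Type-III F-tests with Satterthwaite denominator df (documented as
approximate). Backward elimination removes, one at a time, the least
significant interaction at p > α among those not nested in a retained
higher-order interaction, highest order first, until all retained
interactions are significant; main effects are never removed; the trace
is recorded and is deterministic given the data. Post hoc contrasts are
obtained by re-leveling the reference condition and refitting — the same
model, re-parameterized — with no multiplicity correction by default (a
`p_adjust` argument exists). Visual-only group comparisons use Welch's
unequal-variance t-test.

## The synthetic-data generators

The generators exist so every stage is testable without recorded
material. What they emulate, and what they do not:

* **CV tokens**: duration drawn from a truncated normal (mean 856 ms,
  range 728–941 ms); a 140-ms consonant segment whose energy concentrates
  in a consonant-specific band (band noise for fricatives, a 15-ms burst
  for stops, a low harmonic murmur for nasals) followed by an /i/-like
  harmonic vowel at F0 = 238 Hz with formants at 270/2290/3010 Hz.
  Tokens carry speech/consonant/vowel spans by construction. They are
  acoustic caricatures: no coarticulation, no amplitude contour, no
  talker variability — sufficient for level, filtering and spectral
  tests, not for perceptual realism.
* **Attenuation profiles**: ≈0 dB below 1 kHz, a logistic shelf rising
  over 1–2.5 kHz, plus a log-frequency Gaussian bump (width 0.45
  octaves). Shelf and bump amplitudes solve a 2×2 linear system so the
  2–16 kHz mean and the peak one-third-octave band mean are hit exactly
  by construction. The fabric-like default targets an 8.0 dB band mean
  with its peak band at 3150 Hz; hospital-like 2.4 dB with a high bump at
  8 kHz; transparent-like 5.9 dB peaking at 16 kHz. Arbitrary targets are
  available via `kind = "parametric"`.
* **Recording pairs**: speech-shaped noise passed through an order-512
  realization of the profile (well above the order-128 analysis filter,
  so design error does not contaminate the ground truth) plus independent
  measurement noise at −60 dB relative to the reference RMS.
* **Landmarks**: a stylized face with a raised-cosine mouth-aperture
  cycle, proportional jaw drop, and seeded Gaussian detector jitter
  (default 0.3 px). At zero aperture the inner-lip rims coincide.
* **Listeners**: each articulatory feature is transmitted independently
  with probability plogis(baseline + condition effect + group offset +
  subject intercept). If all three features are transmitted the token is
  fully resolved and the response equals the target; otherwise the
  response is uniform over the consonants consistent with the transmitted
  features. The full-resolution rule exists because /h/ and /∫/ share all
  three feature values — feature identity alone cannot separate them, and
  the model is required to be exact at probability 1. Conditional
  independence of the channels is an explicit simplification, not a claim
  about human perception; the default condition-effect preset (auditory
  damage ordered hospital < transparent < fabric, loading on place; a
  place bonus only when the mouth is visible; visual-only place ≫
  voicing/manner) reproduces the expected qualitative ordering and is
  meant for demonstrations, not calibration to any human dataset.

All generators are pure functions of their parameters and a seed.

For estimator-calibration studies (bias, interval coverage, type-I
error), `simulate_rau_scores()` draws score tables directly from the
mixed model's own generative form (Gaussian subject intercepts and
residuals on the RAU scale, defaults 7 RAU each — the scale of
between-subject spread such scores show at 36–72 trials per cell). This
is the right generator for those questions: it makes "truth" exact on the
model's own scale. The feature-channel cohort path is separately checked
end to end (a configured deficit recovered within its confidence
interval; zero audiovisual benefit when the visual channel is disabled).

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen to keep Monte-Carlo error
well inside the tolerances: 60-s recording pairs for sub-dB attenuation
recovery; 10,000 trials for listener-model consistency (3 SE bands);
200 replicates of 60 subjects × 2 conditions for bias and coverage of a
−10 RAU effect; 300 null replicates for the 5% type-I check; 10-frame
landmark sequences for the occlusion invariants.

## What passing tests show — and what they do not

Green tests demonstrate that the pipeline is internally exact (levels,
SNR, scoring identities), that the estimators recover what the generators
planted, and that the inference stage is calibrated on data from its own
generative form. They do not validate the generators as models of human
listeners or of physical masks: real confusion data have feature
dependencies, response bias and lapses the listener model deliberately
lacks, and real mask spectra have fine structure the smooth profiles do
not. Results on deposited recordings of physical masks can be reproduced
by pointing `estimate_attenuation()` plus `summarize_attenuation()` at
the paired WAV files; the packaged stand-ins for that workflow are
synthetic and labelled as such.

## Known limitations

* Sample rate is fixed at 44.1 kHz by design (the 16 kHz one-third-octave
  band must fit under Nyquist); inputs should be resampled on load.
* Attenuation recovery above ~12 kHz is leakage-limited (see above).
* The windowed-mask cutout is a dilated bounding box, not a traced
  product-specific window shape.
* Satterthwaite df and the elimination path are conventions; other
  toolchains may retain a different final model on the same data.
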