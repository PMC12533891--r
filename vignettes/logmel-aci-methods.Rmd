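---
title: "Methods: the Log-Mel Acoustic Complexity Index pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Log-Mel Acoustic Complexity Index pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logmelaci)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were resolved, and what the
synthetic test regime does and does not demonstrate about real field
recordings.

## The problem

Many songbirds concentrate vocal activity around sunrise (the dawn
chorus), sing least at midday, and partially resume toward dusk and
night. Two complementary ways to quantify that diel pattern from audio
are (a) classifying recordings of one species by period, and (b)
summarizing each recording with an eco-acoustic index and comparing the
index across periods. Classical indices such as the Acoustic Complexity
Index (ACI) were designed to contrast whole soundscapes, not short single
vocalizations of one species, and they respond mainly to intensity
fluctuation on a linear frequency axis. The index at this package's core
instead measures spectral change on a perceptually warped, log-compressed
representation, which makes it track vocal *rhythm* — syllable rate and
call intervals — the very quantity that varies across the day.

## Representations

All analysis starts from a windowed short-time Fourier magnitude
(`stft_magnitude()`). Defaults are a 1024-sample Hann window with a
512-sample hop at 22050 Hz (46 ms / 23 ms), standard bioacoustics
settings that resolve bird syllables (tens of milliseconds) while keeping
~21.5 Hz bin spacing; every function takes its own `frame_params` so
nothing depends on these silently. Frames are centered (half-frame
zero-padding), so frame *t* sits at sample `t * hop`.

The Mel filterbank (`mel_filterbank()`) uses the HTK mapping
`mel(f) = 2595 log10(1 + f/700)` with 20 triangular filters whose apexes
are equally spaced in Mel between 0 Hz and Nyquist. The filter count is
part of the index's definition; the band edges default to the full
spectrum because bird energy commonly spans 1–10 kHz and narrowing the
band is a dataset decision, exposed as `fmin_hz` / `fmax_hz`. Filters
have unit apex; an area-normalization flag exists but the index is a
within-representation ratio, so normalization mostly cancels.

Two distinct logarithms appear deliberately. The Log-Mel representation
is `log(1 + E)`: it is zero at zero energy, non-negative, and bounded
near silence, which the index's denominator needs. The MFCC cepstrum
(`mfcc()`) uses `log(E + 1e-10)` feeding a DCT-II, the standard cepstral
form; with constant band energies `e` it gives `C_0 = 20` and all higher
coefficients zero, a closed form the tests pin. Delta and delta-delta
coefficients (`delta_coeffs()`) use the regression-slope form with
half-width `N = 2` and replicate-padded edges so all three matrices share
a shape.

## The two indices

`aci_traditional()` implements the ratio form: per frequency bin, the sum
of absolute frame-to-frame differences divided by the bin's intensity
sum, summed over bins, within clumps of frames (default: the whole
recording, appropriate for short single vocalizations). A printed
non-normalized product variant of this index exists in parts of the
literature; it is available behind `literal_eq9 = TRUE` for audit, but
the ratio is the established definition and the default — the product
form is not gain-invariant, which disqualifies it for cross-recording
comparison.

`logmel_aci_frames()` computes, per frame transition,
`Σ_k |LogMel(k,t+1) − LogMel(k,t)| / Σ_k LogMel(k,t)`. The denominator is
the frame at *t*, exactly as the defining ratio is written. Three
numerical decisions matter:

* **Silence guard.** Frames whose Mel-band sum is below `1e-12` yield 0
  and are counted in `silent_frames` instead of dividing. On digitally
  silent audio this is exact; on *nearly* silent frames (a window
  catching the tail of a syllable against digital silence) the
  denominator can be tiny but above the guard, and the ratio explodes.
  Real recordings always carry a noise floor that bounds the denominator,
  so the package's rhythm fixtures add 20 dB background noise rather than
  pretending digital silence is representative.
* **Edge trimming.** With centered frames, the half-frame zero padding
  manufactures an onset and offset transient; `trim_edges = TRUE`
  (default) drops the affected first/last frames so a steady tone scores
  ~0 (`logmel_aci(gen_tone(2000, 1))` is about `5e-5`) instead of being
  dominated by two artificial transitions.
* **Aggregation.** The recording-level value is the *mean* over frames
  (sum available). The mean is duration-invariant, which any comparison
  across recordings of different lengths requires.

Scale behavior is asymmetric by design: the traditional ratio is exactly
invariant to gain, while `log(1 + cE) ≠ log(1 + E) + const`, so the
Log-Mel index is not. The test suite asserts the former and pins the
latter with regression values; users should level recordings (the
comparison functions don't re-gain audio) or rely on the within-dataset
consistency of their recording chain.

## Preprocessing

**Spectral subtraction.** `|X|^p = max(|Y|^p − |D|^p, β|D|^p)` with the
noisy phase reused and weighted overlap-add resynthesis (division by the
accumulated squared window, exact wherever coverage is nonzero — the
zero-profile case reconstructs to ~1e-15). The noise spectrum `D` is the
per-bin mean of `|Y|^p` over the first `n_noise_frames` frames (default
5), exposed as its own step so a separate noise-only clip can supply it.
`p = 2` is power subtraction, `p = 1` amplitude subtraction; `β = 0` is
half-wave rectification. One behavior deserves emphasis: subtracting a
noise *average* from stochastic noise leaves the rectified residual —
for white noise at `p = 2` the residual power is `e^{-1}` of the input
(about 57% RMS) — because individual frames fluctuate around the mean.
That is a property of the method, not a defect of the implementation,
and a test asserts the residual at its theoretical level. The method
genuinely flattens *stationary, tonal* interference (machinery hum,
steady wind tones): on the package's hum fixture the residual is ~7%
RMS. An adaptive per-frame exponent has been proposed for such methods
but lacks a settled formulation; the exponent here is fixed per call.

**Endpoint detection.** Short-time energy `Σ x²` and zero-crossing count
(with `sgn(0) = +1`, so digital silence scores 0) are min-max normalized
over the whole recording — which is what makes the decision exactly
gain-invariant — combined as `w·E + (1−w)·Z` (default `w = 0.5`), and
thresholded at `mean + 0.5·sd` of the combined series. An `mode = "or"`
variant thresholds each feature separately and takes the union, for the
literal either/or reading of the rule; the combined form is the default
because the threshold statistic is defined on the weighted average.
Voiced runs shorter than 3 frames are discarded; surviving runs map to
samples using the full window support of their first and last frames —
a voiced frame's trigger can sit anywhere in its window, and the wider
interval is the conservative choice for extraction.

Two practical caveats the synthetic experiments surfaced, documented
here because they will bite on real data too: (1) against *white*
background noise the zero-crossing cue inverts — broadband noise crosses
zero roughly every other sample, more often than any band-limited bird
syllable — so with white-ish backgrounds, `energy_weight = 1` is the
better setting; low-frequency (pink/wind-like) backgrounds restore the
intended behavior of the ZCR term. (2) boundary accuracy is limited by
the syllable's amplitude envelope: a syllable that fades in over 100 ms
is genuinely inaudible at its nominal onset, and no energy detector will
place the boundary there. The package's planted-segment fixtures use
flat-topped syllables over pink noise, and there the detector recovers
100% of boundaries within one hop at 20 dB SNR.

**Augmentation.** `time_stretch()` is a phase vocoder (magnitude
interpolation with phase re-accumulation from measured instantaneous
frequency; 1024/256 analysis geometry), so duration scales by `1/speed`
while spectral peaks stay put — the stated requirement for rhythm-safe
augmentation. A plain resampling mode exists but transposes pitch and is
flagged as non-conforming. `time_shift()` displaces at constant length
with zero fill. `augment_to_minimum()` cycles seeded random
stretch ∈ [0.8, 1.2] and shift ∈ [0, 100] ms over a class until its total
duration reaches a floor (e.g. 20 minutes), keeping originals and
logging every parameter draw.

## The synthetic study regime

`gen_diel_dataset()` emulates a labeled diel recording campaign. Each
synthetic species is a chirp-train "song type": Hann-enveloped linear FM
syllables (60 ms) in a species-specific band (800 Hz sweep starting at
1, 2, 3... kHz) at a species-specific base rate (2, 2.5, 3... per
second), with onsets jittered uniformly within half of each rhythmic
slot. Periods modulate the rate: dawn ×3, night ×2, noon ×1 — the
dawn-chorus ordering — under 20 dB white background noise for all
periods, so the constructed contrast lives purely in rhythm, the
mechanism the Log-Mel index claims to capture, not in loudness or SNR.
The default corpus is 3 species × 3 periods × 5 recordings of 3 s at
22050 Hz, seed 7: large enough for stable group means, small enough that
the full test suite runs in seconds.

On this regime the Log-Mel index recovers dawn > night > noon for every
species, and its normalized between-period spread (range of period means
over pooled within-period sd, `diel_spread()`) exceeds the traditional
index's by roughly an order of magnitude. What this does **not** show:
that real recordings order the same way (real diel differences involve
repertoire, amplitude and background changes the generator deliberately
holds fixed), nor that the index separates species — only that *given*
a rhythm difference, the Log-Mel construction amplifies it relative to
the linear-spectrum ratio. The null regime (equal multipliers) is the
corresponding control: there the orderings are noise.

## Classification framework

Recordings become fixed-length vectors by pooling each of the
MFCC/delta/delta-delta rows to (mean, sd) — 78 dimensions at the
13-coefficient default. The two-layer model fits a species classifier on
everything and one period classifier per species; prediction routes
through the predicted species, and the returned table records which
layer-2 model ran so misroutings are auditable. Scoring defaults to
period-only ("was the period right, whichever model ran"), with a strict
both-labels mode; end-to-end strict accuracy can never exceed layer-1
accuracy. Splits are stratified per (species, period) cell at 8:2 and
seeded. The default classifier is a deterministic 1-nearest-neighbor
(exact distance ties break toward the lexicographically lowest label);
multinomial logistic regression and caller-supplied fit/predict pairs
plug in behind the same interface. Deep networks are intentionally out
of scope — the framework, not the capacity of any particular classifier,
is what the package implements; on the separable synthetic corpus the
1-NN validation accuracy is 1.0 at both layers, a property of the
generator's separability, not a benchmark claim.

Metrics are one-vs-rest confusion counts feeding accuracy, precision,
recall and F1, macro-averaged by default (F1 from the averaged precision
and recall); micro averaging pools counts, making micro accuracy equal
the fraction of exactly correct predictions.

## Known limitations

* The Log-Mel index's gain sensitivity (above) means absolute values are
  only comparable within a consistently leveled dataset.
* Spectral subtraction assumes stationary noise; non-stationary
  suppression (Wiener filtering, source separation) is out of scope.
* The endpoint detector is a two-feature threshold rule; overlapping
  songs or gradual fade-ins will blur boundaries, as the envelope
  analysis above quantifies.
* Synthetic chirp trains have no harmonic stacks, formants, reverberation
  or competing callers; passing tests here validates the computation
  chain, not field robustness.
* WAV support covers 16-bit PCM and 32-bit float; convert other formats
  externally.
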