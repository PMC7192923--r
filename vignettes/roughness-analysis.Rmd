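---
title: "Quantifying kilohertz amplitude modulation in vocalizations and its physiological impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kilohertz amplitude modulation in vocalizations and its physiological impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalrough)
```

## The problem

Distress calls of the bat *Carollia perspicillata* are short (milliseconds),
harmonically structured, downward frequency-modulated syllables emitted in
bouted sequences. A large fraction of them carries sinusoidal amplitude
modulation (AM) near 1.7 kHz — an analogue, more than ten times faster, of
the 30–150 Hz "roughness" of human screams. This package implements the full
measurement chain for that phenomenon: detecting and segmenting syllables,
quantifying their temporal and spectral modulation structure, classifying
rough (fast-AM, "fAMV") versus smooth (slow-AM, "sAMV") syllables, removing
the modulation from a sound while preserving its spectro-temporal design
(MPS filtering / demodulation), and measuring physiological consequences:
heart-rate acceleration (ECG), frequency-following responses (iEEG), and
cochlear sensitivity (DPOAE). Because no real recordings ship with this
package, every input is produced by a synthetic generator that plants known
ground truth, and the package's tests are parameter-recovery tests against
that ground truth.

## The synthetic generators and what they emulate

`make_syllable()` renders a harmonic stack (amplitudes halving per harmonic)
riding a fundamental contour — linear downward sweep ("FM", default
28 → 18 kHz), a 40% plateau followed by a sweep ("qCF-FM"), or a sinusoidal
contour ("SFM", 3 kHz depth at 400 Hz) — multiplied by the AM modulator

\[ m(t) = \frac{1 + d\,\sin(2\pi f_{am} t + \varphi)}{1 + d}, \]

normalized by \(1 + d\) so that peak amplitude is depth-invariant (level
comparisons then reflect modulation, not gain). The AM phase \(\varphi\) is
drawn per syllable and recorded in the ground truth. Corpora
(`make_distress_corpus()`) draw per-syllable labels (fast-AM with
probability `fam_fraction`, default 0.477 for the distress-like corpus and
0.063 for the social-like corpus), AM rates from a normal distribution
centered at 1.75 kHz (SD 200 Hz, clipped to 1.2–2.4 kHz), depths 0.7–1 for
fast and slow drifting modulations (50–300 Hz, depth 0.2–0.5) otherwise,
with log-normal sequence lengths (median 60 syllables). A `position_bias`
parameter tilts fast-AM syllables toward the sequence start via exponential
position weights, emulating the left skew of rough syllables in real
sequences. Stimulus sequences are 11 bouts of 6 syllable repetitions with
14 ms within-bout and 80 ms between-bout silent gaps and 0.2 ms edge fades;
gaps are interpreted offset-to-onset (an onset-to-onset reading of the 80 ms
inter-bout interval could not contain a six-syllable bout).

ECG trials realize beat times from an instantaneous rate
\(r(t) = \text{baseline} + \text{gain}\,g(t - t_0)\) with a causal
double-exponential kernel (0.5 s rise, 2 s decay, peak normalized), stamping
each beat with a biphasic, dominantly negative QRS template; movement
artifacts are spike pairs closer than 62 ms. The baseline is 480 bpm —
chosen so the 62 ms (960 bpm) artifact bound sits far above the simulated
physiological range. iEEG trials superimpose, on 1/f background noise, a
per-syllable evoked transient and a stimulus-locked sinusoid at the
stimulus AM rate (`ffr_gain`; zero for demodulated stimuli), with at least
1.5 s of silent baseline before the first onset. Ear-canal epochs contain
the two DPOAE primaries (f2/f1 = 1.25 exactly) plus, when f2 lies at or
above the 5 kHz cochlear cutoff, a cubic distortion product at 2f1 − f2;
stimulus frequencies are snapped to multiples of `5 * rate / epoch_len` so
that f1, f2 and the DP all fall exactly on FFT bins of one 8192-point
epoch — the standard rig trick that keeps the strong primaries from leaking
across the spectrum. None of this attempts to reproduce the true acoustic
statistics of *C. perspicillata* beyond the features the pipeline measures:
no vocal-tract model, no nonlinear phonation, no colony noise. Passing
tests demonstrate that the measurement chain recovers planted structure at
realistic scales, not that it would reproduce any particular corpus's
statistics from raw recordings.

## Feature extraction

Syllables are segmented where the smoothed analytic-signal envelope stays
at or above 4.1% of digital full scale (the threshold is full-scale
relative, not per-file — so absolute level matters), with sub-threshold
runs shorter than 1 ms bridged and segments shorter than 0.5 ms dropped as
clicks (an automatic stand-in for manual revision of detections). Consecutive
syllables within 30 ms share a bout.

The amplitude envelope is the analytic-signal magnitude, low-pass filtered
below 5 kHz and resampled to 0.1 ms. The temporal modulation spectrum (TMS)
is the squared-magnitude FFT of the mean-subtracted envelope, zero-padded
to 1 s so the grid is 1 Hz for every syllable, and normalized to unit total
power over 0–4 kHz. The best modulation frequency (BMF) is the TMS argmax
within the 1.15–2.45 kHz frequencies of interest (FOI), and the FOI area is
the trapezoidal area over that band. Note the 1 Hz grid does not confer
1 Hz accuracy: a millisecond-scale envelope has a spectral mainlobe of
order 1/duration, and the argmax wanders a few hertz with the AM phase;
recovery tests therefore use a 10 Hz tolerance.

Frequency spectra are magnitude FFTs linearly interpolated onto a fixed
200 Hz grid and peak-normalized. The harmonic-to-noise difference (HND) is
the maximum absolute difference between the normalized spectrum and its
5-point moving average (shrinking windows at the edges); being computed on
normalized spectra it is gain-invariant. Spectral regularity is measured on
the autocorrelation of the mean-subtracted normalized spectrum over lags to
±10 kHz: local maxima at topographic prominence 0.025 on positive lags give
the median inter-peak distance (MIPD; the mean is available via
`summary = "mean"`). Two physical regimes matter here. When the FM sweep
extent is small relative to the AM rate (quasi-CF syllables), the AM
sidebands survive in the time-integrated spectrum as a comb at the AM rate
and MIPD recovers it. When the sweep is broad (the default corpus regime),
stationary-phase smearing turns the comb into ripple at the chirp rate
divided by the AM rate, fewer than two prominent peaks survive, and MIPD is
flagged undefined — so on realistic material the metric is defined only on a
subset of rough syllables. A further limit is intrinsic to a pure sinusoidal modulator: it has
only first-order sidebands, so the second autocorrelogram peak rests on
sideband-by-sideband products and clears the 0.025 prominence only for
depths of roughly 0.7 and above.

Band levels (`band_spl()`) use a single-pass 3rd-order Butterworth bandpass
(order exactly as specified, not zero-phase) and express the filtered RMS
in dB SPL against a 94 dB SPL calibrator tone under the recording's
full-scale calibration.

## MPS computation and demodulation

The short-time Fourier transform uses window length 64, FFT length 64 and
hop 1 (periodic Hann), on the signal centered in a nominal 0.5 s zero
buffer. The short window is what places 1.7 kHz periodicity on the
*temporal*-modulation axis of the MPS rather than resolving it spectrally.
One boundary convention is fixed throughout: the buffer holds
`round(pad_to_s * rate) + 63` samples, so the frame count is exactly
`round(pad_to_s * rate)` — a highly composite number, which the FFT along
the frame axis (up to 150 000 frames) needs to be tractable. The MPS is the
log of the squared magnitude of the 2D FFT of the log-magnitude STFT;
temporal modulation is in Hz (frame rate = audio rate at hop 1) and
spectral modulation in cycles/kHz (bin spacing rate/64). Magnitudes are
floored at 1e−12 of the maximum for display purposes.

Demodulation nullifies the complex 2D-FFT coefficients for all temporal
modulations with absolute value between 1 and 4 kHz (all spectral
modulations — the band that covers the ~1.7 kHz periodicities), inverts the
2D FFT, exponentiates to recover magnitudes, and estimates the sound from
those magnitudes by weighted overlap-add with iterative phase
re-estimation: phases start at the original STFT's and are replaced, for 16
iterations, by the phases of the resynthesized sound's STFT. Operating on
the complex coefficients rather than on the real log-power map avoids
double-counting the squaring; the alternative nullifies the same band. Two
numerical choices required care. First, the log floor for *this* operation
is 1e−3 of the maximum (a 60 dB dynamic range): synthetic silence is
exactly zero, and an unbounded floor makes the silence-to-syllable step in
the log STFT hundreds of dB deep, whose Gibbs ringing under band removal
corrupts the desired magnitudes inside the syllable (real recordings have
noise floors; 60 dB emulates one). Second, a single overlap-add pass with
the original phases leaves 6–12% synthesis error because a
modified-magnitude STFT is not self-consistent; the iterative estimate
converges to 1.3–1.6% for the three stimulus variants, within the 2%
bound the construction is held to. The synthesis error is
\(\sum(|S_d| - |S_o|)^2 / \sum |S_d|^2\), desired versus resynthesized
magnitudes, as a percentage. Outputs are trimmed to the input's extent and
RMS-matched to it.

Group contrasts of MPS maps (`mps_group_contrast()`) compute per-cell
Cliff's delta and flag |d| > 0.474 as large (0.474, the conventional large-effect
boundary, is used throughout; 0.478 appears as a variant in the
literature). Full-resolution maps
have millions of cells, so the contrast runs on a cropped
(|temporal modulation| ≤ 6 kHz) and block-averaged map; contrast maps of this kind are
display-resolution objects.

## Classification and position statistics

Feature vectors are TMS power averaged into 10 Hz bins on 0–4 kHz (401
values, unit sum) — fine enough to resolve the FOI, small enough for a
100-exemplar SVM. The classifier is an RBF-kernel SVM without feature
standardization, box constraint 1. The kernel coefficient defaults to
gamma = 10 (kernel scale ≈ 0.32): unit-sum TMS vectors have pairwise
squared distances of order 0.03, and the conventional kernel scale of 1
underfits at that geometry (5% CV error on separable sets versus 0%).
Cross-validation is stratified, seeded, 10-fold.

The position analysis maps syllable i of an N-syllable sequence to
\((i-1)/(N-1)\) (0.5 for N = 1; the alternative reading i/N is available in
the sources), pools fast-AM positions across 100 within-sequence label
shuffles into an expected distribution (shuffles preserve per-sequence
label counts exactly), and compares observed versus expected with a
two-sample Kolmogorov–Smirnov test; per-sequence fast-AM proportions in the
first versus second half are compared by paired signed-rank.

## Physiology

QRS detection operates on the smoothed (1 ms) analytic envelope of the ECG:
events are local maxima above a threshold that is at least two noise SDs
(robust MAD estimate after a two-pass spike exclusion)
and at least 30% of the robust spike amplitude (the envelope's 99.9th
percentile). The second criterion exists because a bare 2 SD threshold
admits chance Gaussian excursions on any minutes-long trace; with it,
planted beats are recovered within ±2 ms at SNR 10 with no extras.
Instantaneous heart rate is 60/interval, assigned at the later beat,
linearly interpolated to a 0.5 s grid from −5 to +10 s around stimulus
onset. Any interval under 62 ms (over 960 bpm) marks the whole trial as a
movement artifact and excludes it. The response area integrates the
baseline-subtracted curve over the first 10 s (baseline = mean over
[−5, 0) s; a raw-area mode exists). Condition summaries average areas over
valid trials per animal, z-score within animal for display, and compare
conditions by paired signed-rank across animals.

The iEEG spectrogram is multitaper (5 DPSS tapers, time-bandwidth 3),
window 50 ms, step 5 ms — about 120 Hz bandwidth, comfortably resolving the
1.6–2 kHz FFR band at 9.6 kHz sampling. Power is baseline-corrected by
subtracting each frequency's mean over the pre-stimulus silence (≥ 1.5 s),
and the FFR band power is the mean corrected power in 1.6–2 kHz over the
stimulus extent. Evoked averages take 20 ms windows from each syllable
onset.

DPOAE analysis coherently averages the 100 epochs, takes a plain
rectangular FFT at native resolution (with bin-centered stimulation this
is leak-free), reads the DP at its bin, and estimates the noise floor as
the mean amplitude of the 10 nearest bins per side, excluding the DP bin
and one neighbor each side. At the native 23.4 Hz resolution those 20 bins
span about ±240 Hz; a literal "20 points within a 100 Hz span" is not
realizable at this epoch length. Detection requires the DP to clear the
floor by 6 dB (configurable); under the null the DP bin is a single
Rayleigh draw against the mean of twenty, so isolated chance detections at
a few percent per grid point are expected and the DPgrams are read
accordingly.

## Statistics

Cliff's delta is computed by a rank-sum identity exactly equivalent to full
pairwise enumeration (ties count half each way); the brute-force path is
retained and tested against it. Bins: negligible < 0.147 ≤ small < 0.33 ≤
medium < 0.474 ≤ large on |d|, boundaries assigned downward (the conventional
inequalities are strict). Paired/unpaired comparisons use two-sided
signed-rank / rank-sum tests with exact small-sample p-values where the
standard implementation provides them (n < 50, no ties) and the normal
approximation otherwise; an all-ties paired comparison is flagged undefined
rather than given a p-value.

## Orchestration, determinism, and problem sizes

`run_acoustics()` and `run_physiology()` execute the whole analysis at desk
scale: generate corpora, segment, extract features, train and apply the
classifier, run position statistics and group contrasts; build the six
stimulus sequences (three variants × natural/demodulated, each gated on
synthesis error ≤ 2%), simulate ECG and iEEG cohorts, and assemble DPgrams.
Every stage derives its seed from the master seed, and identical
configurations yield identical reports. Defaults follow the full experimental design
(40-sequence distress and 25-sequence social corpora; 12 ECG animals × 10
trials × 6 conditions; 11 iEEG animals). The test suite exercises the same
code at smaller sizes chosen for turnaround — e.g. 8-sequence corpora,
8 ECG animals × 2 trials (the smallest design in which a uniformly ordered
paired signed-rank reaches p < 0.01), 200-trial artifact-rate batches —
sizes at which the planted effects are still unambiguous.

## Known limitations

Absolute corpus statistics (the 47.7% / 6.3% fast-AM fractions, median BMF
1.75 kHz, effect sizes) are recoverable here only because they are planted;
nothing about real recordings follows from these tests. The synthetic AM is
strictly sinusoidal, so envelope harmonics present in real rough calls are
absent, which narrows the depth range over which spectral-comb metrics
(MIPD) are defined. Demodulated sounds retain a residual envelope ripple
(relative depth ≈ 0.3 from an input at 0.9) because the original phase
structure partially re-imposes the modulation during resynthesis — the
planted physiological contrasts are driven by the generator gains, not by
this residual. The segmentation stand-in replaces manual revision
with a minimum-duration rule and may differ on pathological
inputs.
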