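# vocalrough

Analysis of fast ("roughness-like") amplitude modulation in animal
vocalizations and of its physiological impact, built around the case of bat
(*Carollia perspicillata*) distress calls, which carry sinusoidal amplitude
modulation (AM) near 1.7 kHz.

The package is aimed at bioacousticians and auditory neurophysiologists who
need the full measurement chain in one place:

- **Synthetic generators with planted ground truth** for every input the
  chain consumes: harmonically structured downward-FM syllables with or
  without kilohertz AM, bouted stimulus sequences (11 bouts × 6 syllables,
  14 ms / 80 ms silent gaps), vocalization corpora with a planted fast-AM
  fraction and position bias, ECG trials with a planted heart-rate response,
  iEEG trials with a planted frequency-following response (FFR), and
  two-tone ear-canal epochs with a planted cubic distortion product.
- **Segmentation**: amplitude-threshold syllable detection (4.1% of full
  scale, 1 ms gap bridging) and bout grouping.
- **Per-syllable features**: amplitude envelope (0.1 ms resolution),
  temporal modulation spectrum (TMS) with best modulation frequency (BMF,
  argmax in the 1.15–2.45 kHz frequencies of interest) and FOI area,
  200-Hz-resolution spectra, harmonic-to-noise difference (HND), spectral
  autocorrelograms with median inter-peak distance (MIPD), and calibrated
  band sound-pressure levels.
- **Modulation power spectra (MPS)** from hop-1, window-64 STFTs;
  modulation-band filtering and weighted-overlap-add resynthesis with
  iterative phase re-estimation ("demodulation": nullify temporal
  modulations of 1–4 kHz, keep the spectro-temporal design, synthesis
  error below 2%); per-cell Cliff's delta contrasts of MPS groups.
- **Classification**: an RBF-kernel SVM on TMS feature vectors separating
  fast-AM from slow-AM syllables, plus the sequence-position analysis
  (within-sequence label permutations, Kolmogorov–Smirnov test).
- **Physiology**: QRS detection, instantaneous heart rate (60/interval),
  the 960 bpm movement-artifact trial rejection, baseline-subtracted
  response areas; multitaper (5 DPSS tapers, NW = 3) spectrograms with
  silent-baseline correction and 1.6–2 kHz FFR band power; evoked
  averages; DPOAE amplitudes with noise floors and DPgrams.
- **Statistics**: Cliff's delta (rank-based, with the published
  negligible/small/medium/large bins) and two-sided signed-rank /
  rank-sum tests.

The central quantity throughout is the **temporal modulation spectrum**
\(P(f) \propto |\mathcal{F}\{e(t) - \bar e\}|^2\) of a syllable's amplitude
envelope \(e(t)\), normalized to unit total power on 0–4 kHz, and its
two-dimensional sibling, the **modulation power spectrum**
\(\mathrm{MPS}(f_t, f_s) = \log |\mathcal{F}_2\{\log|S(t,f)|\}|^2\) of the
log-magnitude STFT \(S\), whose temporal-modulation axis \(f_t\) (Hz)
carries the AM and whose spectral-modulation axis \(f_s\) (cycles/kHz)
carries the harmonic structure.

## Worked example

```r
library(vocalrough)

# a 5 ms distress-like syllable, AM at 1.7 kHz, depth 0.9
syl <- make_syllable(syllable_spec(am_rate_hz = 1700, am_depth = 0.9), seed = 2)
syllable_features(syl, calibration_db_fs = 94)[, c("bmf_hz", "foi_area",
                                                   "peak_frequency_hz", "hnd")]
#>   bmf_hz foi_area peak_frequency_hz   hnd
#> 1   1706    0.901             26400 0.273

# render and re-detect the stimulus sequence
seqw <- make_stimulus_sequence(syl, sequence_layout())
segs <- segment_syllables(seqw)
cat(nrow(segs), "syllables in", max(group_bouts(segs)$bout), "bouts\n")
#> 66 syllables in 11 bouts

# strip the 1-4 kHz temporal modulations, keep the FM contour
syl192 <- make_syllable(syllable_spec(am_rate_hz = 1700, am_depth = 0.9,
                                      rate_hz = 192000), seed = 2)
dem <- demodulate(syl192)
dem$report$synthesis_error_pct
#> [1] 1.28
```

The feature row says: the envelope periodicity is recovered at 1.706 kHz
(planted: 1.7 kHz; the argmax of a millisecond envelope wanders a few hertz
by spectral leakage), 90% of envelope modulation power falls in the
1.15–2.45 kHz band, the strongest carrier is at 26.4 kHz, and the spectrum
deviates from its 5-point smooth by 0.27 of the peak. The demodulation
report confirms the resynthesis is faithful to the filtered target within
1.28% energy error (the construction requires ≤ 2%).

On the physiology side:

```r
tr <- make_ecg_trial(ecg_trial_spec(response_gain_bpm = 80, seed = 3))
h  <- hr_curve(detect_qrs(tr), stimulus_onset_s = 5)
cat(sprintf("HR response area: %.1f bpm*s (valid trial: %s)\n",
            h$response_area, h$valid))
#> HR response area: 252.8 bpm*s (valid trial: TRUE)
```

which recovers the planted response kernel's integral (251.7 bpm·s) within
half a percent. `run_acoustics()` and `run_physiology()` chain all stages
over full synthetic cohorts and report ground-truth recovery alongside the
group statistics.

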