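Package: vocalrough
Title: Fast Amplitude-Modulation ('Roughness') Analysis of Animal Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and quantifying fast (kilohertz-range)
    amplitude modulations in animal vocalizations and for measuring their
    physiological impact. Provides synthetic generators for harmonically
    structured frequency-modulated syllables, bouted stimulus sequences,
    ECG, intracranial EEG and ear-canal recordings with planted ground
    truth; amplitude-threshold syllable segmentation; temporal modulation
    spectra, 200-Hz-resolution spectra, harmonic-to-noise differences and
    spectral autocorrelograms; modulation power spectrum (MPS) computation,
    modulation-band filtering and weighted-overlap-add resynthesis
    (demodulation); an RBF-kernel support-vector classifier of rough
    versus smooth syllables with sequence-position statistics; QRS
    detection and heart-rate response areas; multitaper
    frequency-following-response analysis; distortion-product otoacoustic
    emission (DPOAE) amplitudes; and Cliff's delta effect sizes with
    nonparametric tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
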