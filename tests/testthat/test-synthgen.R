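# Synthetic generators: planted structure must be present and
# machine-recoverable, and every generator bit-reproducible under seed.

test_that("syllable AM modulator is planted at the requested rate and depth", {
  syl <- fix_fam_syllable(rate = 1700, depth = 0.9)
  gt <- attr(syl, "ground_truth")
  expect_equal(gt$am_rate_hz, 1700)
  expect_lt(abs(env_depth(syl) - 0.9) / 0.9, 0.05)
  # envelope oscillates at the planted rate
  tms <- temporal_modulation_spectrum(amplitude_envelope(syl))
  expect_lt(abs(tms$bmf_hz - 1700), 25)
})

test_that("unmodulated syllable has a flat envelope away from the ramps", {
  syl <- make_syllable(syllable_spec(am_rate_hz = 0), seed = 1)
  v <- amplitude_envelope(syl)$values
  i <- seq(floor(length(v) * 0.15), ceiling(length(v) * 0.85))
  expect_lt((max(v[i]) - min(v[i])) / mean(v[i]), 0.01)
})

test_that("SFM variant carries a sinusoidal frequency contour", {
  syl <- make_syllable(syllable_spec(fm_variant = "SFM",
                                     duration_s = 0.01), seed = 3)
  sp <- signal::specgram(syl$samples, n = 512, Fs = syl$rate_hz,
                         window = signal::hanning(512), overlap = 480)
  A2 <- Mod(sp$S)^2
  keep <- colSums(A2) > 0.01 * max(colSums(A2))
  traj <- sp$f[apply(A2[, keep], 2, which.max)]
  # fundamental ridge (or a harmonic): fit a sinusoid at the SFM rate
  tt <- sp$t[keep]
  fit <- stats::lm(traj ~ sin(2 * pi * 400 * tt) + cos(2 * pi * 400 * tt))
  expect_gt(summary(fit)$r.squared, 0.8)
})

test_that("harmonics above Nyquist are rejected with an explanation", {
  expect_error(make_syllable(syllable_spec(fundamental_start_hz = 60000,
                                           n_harmonics = 3,
                                           rate_hz = 300000)),
               "Nyquist")
})

test_that("AM tone has sidebands at carrier +/- modulation rate", {
  tone <- make_am_tone(20000, 1700, 0.2, 192000)
  P <- Mod(stats::fft(tone$samples))^2
  f <- (seq_along(P) - 1) * 192000 / length(P)
  peak_at <- function(freq) P[which.min(abs(f - freq))]
  floor_p <- stats::median(P[f > 1000 & f < 90000])
  for (fp in c(18300, 20000, 21700))
    expect_gt(peak_at(fp), 1e6 * floor_p)
  # unmodulated control: single peak, no sidebands
  pure <- make_am_tone(20000, 0, 0.2, 192000)
  P0 <- Mod(stats::fft(pure$samples))^2
  expect_gt(P0[which.min(abs(f - 20000))], 1e6 * stats::median(P0[f > 1000 & f < 90000]))
  expect_lt(P0[which.min(abs(f - 18300))], 1e-3 * P0[which.min(abs(f - 20000))])
})

test_that("stimulus sequence realizes the bouted layout exactly", {
  syl <- make_syllable(syllable_spec(), seed = 1)   # 5 ms
  sq <- make_stimulus_sequence(syl, sequence_layout())
  expect_equal(length(attr(sq, "onsets_s")), 66L)
  # silent-gap interpretation: 11*(6*5 + 5*14) ms + 10*80 ms = 1900 ms
  expect_equal(length(sq$samples), round(1.9 * syl$rate_hz))
  # single syllable layout: output is the faded syllable
  one <- make_stimulus_sequence(syl, sequence_layout(1, 1))
  expect_equal(length(attr(one, "onsets_s")), 1L)
  expect_equal(length(one$samples), length(syl$samples))
  # RMS over the syllable support matches the input syllable's RMS
  expect_equal(sqrt(mean(one$samples^2)), sqrt(mean(syl$samples^2)),
               tolerance = 1e-10)
})

test_that("corpus realizes the planted fast-AM fraction and position bias", {
  spec <- corpus_spec(n_sequences = 90, fam_fraction = 0.477, seed = 1)
  gt <- make_distress_corpus(spec, render = "none")$ground_truth
  expect_gt(nrow(gt), 4000)
  expect_lt(abs(mean(gt$label == "fAMV") - 0.477), 0.02)
  # all-slow corpus
  gt0 <- make_distress_corpus(corpus_spec(n_sequences = 3, fam_fraction = 0,
                                          seed = 2),
                              render = "none")$ground_truth
  expect_true(all(gt0$label == "sAMV"))
  # position bias shifts fast-AM syllables left
  gtb <- make_distress_corpus(corpus_spec(n_sequences = 60,
                                          position_bias = 0.8, seed = 3),
                              render = "none")$ground_truth
  expect_lt(stats::median(gtb$norm_position[gtb$label == "fAMV"]), 0.5)
  # empty corpus warns
  expect_warning(make_distress_corpus(corpus_spec(n_sequences = 0)),
                 "empty")
})

test_that("ECG generator plants the requested rate response and artifacts", {
  # constant rate: intervals equal 60/baseline
  tr0 <- make_ecg_trial(ecg_trial_spec(seed = 1))
  iv0 <- diff(attr(tr0, "ground_truth")$beat_times_s)
  expect_lt(max(abs(iv0 - 60 / 480)), 1e-6)
  # response: post-onset intervals shorten
  tr1 <- make_ecg_trial(ecg_trial_spec(response_gain_bpm = 100, seed = 1))
  bt <- attr(tr1, "ground_truth")$beat_times_s
  iv <- diff(bt)
  at <- bt[-1]
  expect_lt(min(iv[at > 5]), min(iv[at <= 5]))
  # artifacts produce sub-62-ms events
  tr2 <- make_ecg_trial(ecg_trial_spec(artifact_rate = 3, seed = 5))
  art <- attr(tr2, "ground_truth")$artifact_times_s
  expect_gt(length(art), 0)
  gaps <- diff(art)[seq(1, length(art) - 1, by = 2)]
  expect_true(all(gaps < 0.062))
})

test_that("iEEG generator honors the silent baseline and plants the FFR", {
  on <- seq(0, 0.5, by = 0.1)
  tr <- make_ieeg_trial(ieeg_trial_spec(ffr_gain = 2, seed = 4), on, 0.05,
                        1700)
  expect_gte(min(attr(tr, "onsets_s")), 1.5)
  # narrowband 1.7 kHz power during syllables exceeds baseline
  fs <- tr$rate_hz
  bp <- function(idx) {
    P <- Mod(stats::fft(tr$samples[idx]))^2
    f <- (seq_along(P) - 1) * fs / length(P)
    mean(P[f >= 1600 & f <= 1800])
  }
  stim_idx <- round((attr(tr, "onsets_s")[1] * fs)):round(((attr(tr, "onsets_s")[1] + 0.05) * fs))
  base_idx <- seq_len(round(1.4 * fs))[1:length(stim_idx)]
  expect_gt(bp(stim_idx), 3 * bp(base_idx))
  # ffr_gain = 0 plants nothing
  tr0 <- make_ieeg_trial(ieeg_trial_spec(ffr_gain = 0, seed = 4), on, 0.05,
                         1700)
  P1 <- Mod(stats::fft(tr0$samples[stim_idx]))^2
  expect_lt(bp(stim_idx) / bp(base_idx), 1e6)  # sanity: finite
  expect_error(make_ieeg_trial(ieeg_trial_spec(), on, 0.05, 5000),
               "Nyquist")
})

test_that("ear-canal generator plants the DP only above the cochlear cutoff", {
  sp_hi <- ear_canal_spec(f2_hz = 18000, seed = 1)
  expect_true(attr(make_ear_canal_epochs(sp_hi), "ground_truth")$dp_planted)
  expect_equal(attr(make_ear_canal_epochs(sp_hi), "ground_truth")$dp_freq_hz,
               2 * sp_hi$f1_hz - sp_hi$f2_hz)
  sp_lo <- ear_canal_spec(f2_hz = 1800, seed = 1)
  expect_false(attr(make_ear_canal_epochs(sp_lo), "ground_truth")$dp_planted)
  # f2/f1 ratio exact
  expect_equal(sp_hi$f2_hz / sp_hi$f1_hz, 1.25, tolerance = 1e-12)
  # zero noise: all epochs identical
  spz <- ear_canal_spec(noise_db = -Inf, seed = 1)
  epz <- make_ear_canal_epochs(spz)
  expect_equal(max(abs(sweep(epz, 2, epz[1, ]))), 0)
})

test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- make_syllable(syllable_spec(am_rate_hz = 1700), seed = 9)
  s2 <- make_syllable(syllable_spec(am_rate_hz = 1700), seed = 9)
  expect_identical(s1$samples, s2$samples)
  c1 <- make_distress_corpus(corpus_spec(n_sequences = 2, seed = 9),
                             render = "none")$ground_truth
  c2 <- make_distress_corpus(corpus_spec(n_sequences = 2, seed = 9),
                             render = "none")$ground_truth
  expect_identical(c1, c2)
  e1 <- make_ecg_trial(ecg_trial_spec(seed = 9, noise_sd = 0.1))
  e2 <- make_ecg_trial(ecg_trial_spec(seed = 9, noise_sd = 0.1))
  expect_identical(e1$samples, e2$samples)
  m1 <- make_ear_canal_epochs(ear_canal_spec(seed = 9))
  m2 <- make_ear_canal_epochs(ear_canal_spec(seed = 9))
  expect_identical(unclass(m1), unclass(m2))
})
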