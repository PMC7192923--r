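# QRS detection, heart-rate curves, multitaper FFR, evoked averages,
# DPOAE amplitudes.

test_that("QRS detection recovers planted beats within 2 ms at SNR 10", {
  spec <- ecg_trial_spec(baseline_bpm = 600, noise_sd = 0.1, seed = 7)
  tr <- make_ecg_trial(spec)
  gt <- attr(tr, "ground_truth")$beat_times_s
  q <- detect_qrs(tr)
  expect_equal(length(q$times_s), length(gt))
  expect_lt(max(abs(q$times_s - gt)), 0.002)
  expect_equal(q$polarity, -1)
})

test_that("flat traces and sub-threshold spikes yield no events", {
  fs <- 9600
  expect_length(detect_qrs(waveform(numeric(fs), fs))$times_s, 0L)
  # spikes at 1.5 x noise SD stay below the 2-SD criterion
  set.seed(3)
  x <- stats::rnorm(10 * fs, 0, 0.1)
  env_sd <- 0.1
  at <- seq(fs, 9 * fs, by = fs %/% 2)
  x[at] <- x[at] + 1.5 * env_sd
  q <- detect_qrs(waveform(x, fs))
  expect_length(q$times_s, 0L)
})

test_that("instantaneous HR is 60 / interval, assigned at the later beat", {
  for (iv in c(0.062, 0.1, 0.125, 0.2)) {
    q <- structure(list(times_s = c(1, 1 + iv), threshold = 1,
                        polarity = -1, noise_sd = 0.1),
                   class = "qrs_series")
    h <- hr_curve(q, stimulus_onset_s = 1, pre_s = 1, post_s = 1)
    expect_equal(max(h$bpm), 60 / iv, tolerance = 1e-9)
  }
  # 62 ms interval: 967.7 bpm, above the 960 bpm artifact bound -> invalid
  q62 <- structure(list(times_s = c(1, 1.062), threshold = 1,
                        polarity = -1, noise_sd = 0.1),
                   class = "qrs_series")
  h62 <- hr_curve(q62, 1)
  expect_gte(max(h62$bpm), 960)
  expect_false(h62$valid)
  # 61.9 ms is strictly below the 62 ms rule
  q61 <- structure(list(times_s = c(1, 1.0619), threshold = 1,
                        polarity = -1, noise_sd = 0.1),
                   class = "qrs_series")
  expect_false(hr_curve(q61, 1)$valid)
})

test_that("trial validity is monotone under added short intervals", {
  times <- seq(0, 15, by = 0.125)
  q <- structure(list(times_s = times, threshold = 1, polarity = -1,
                      noise_sd = 0.1), class = "qrs_series")
  expect_true(hr_curve(q, 5)$valid)
  q_bad <- q; q_bad$times_s <- sort(c(times, 7.03))   # 30 ms to a neighbor
  expect_false(hr_curve(q_bad, 5)$valid)
})

test_that("response area recovers the planted kernel integral", {
  spec <- ecg_trial_spec(response_gain_bpm = 80, response_decay_s = 2,
                         noise_sd = 0.05, seed = 3)
  tr <- make_ecg_trial(spec)
  h <- hr_curve(detect_qrs(tr), stimulus_onset_s = 5)
  tt <- seq(0, 10, by = 0.001)
  planted <- 80 * sum(vocalrough:::hr_response_kernel(tt, 0.5, 2)) * 0.001
  expect_lt(abs(h$response_area - planted) / planted, 0.15)
  # flat train: |area| below 2 bpm*s
  h0 <- hr_curve(detect_qrs(make_ecg_trial(ecg_trial_spec(seed = 4))), 5)
  expect_lt(abs(h0$response_area), 2)
})

test_that("condition summary z-scores within animal and tests across", {
  trials <- do.call(rbind, lapply(1:12, function(a) {
    base <- stats::rnorm(1, 100, 20)        # animal-specific scale
    data.frame(animal = a,
               condition = rep(c("natural", "demodulated"), each = 3),
               area = c(base + stats::rnorm(3, 60, 5),
                        base + stats::rnorm(3, 20, 5)),
               valid = TRUE)
  }))
  s <- hr_condition_summary(trials, c("natural", "demodulated"))
  expect_lt(s$p, 0.01)
  z_by_animal <- tapply(s$per_animal$z, s$per_animal$animal, sum)
  expect_true(all(abs(z_by_animal) < 1e-9))
  # identical conditions: no signal
  tr2 <- trials; tr2$area <- 1
  s2 <- hr_condition_summary(tr2, c("natural", "demodulated"))
  expect_true(is.na(s2$p))
  # single animal: p undefined, areas still reported
  s1 <- hr_condition_summary(trials[trials$animal == 1, ],
                             c("natural", "demodulated"))
  expect_true(is.na(s1$p))
  expect_equal(nrow(s1$per_animal), 2L)
  # empty cells warn
  tr3 <- trials; tr3$valid[tr3$animal == 2 & tr3$condition == "natural"] <- FALSE
  expect_warning(hr_condition_summary(tr3, c("natural", "demodulated")),
                 "no valid trials")
})

test_that("multitaper FFR band power separates planted from control", {
  syl <- make_syllable(syllable_spec(am_rate_hz = 1700, am_depth = 0.9,
                                     rate_hz = 192000), seed = 1)
  sq <- make_stimulus_sequence(syl, sequence_layout())
  on <- attr(sq, "onsets_s"); sd_s <- attr(sq, "syllable_duration_s")
  for (sd in 1:10) {
    tp <- make_ieeg_trial(ieeg_trial_spec(ffr_gain = 1.5, seed = sd),
                          on, sd_s, 1700)
    tc <- make_ieeg_trial(ieeg_trial_spec(ffr_gain = 0, seed = 100 + sd),
                          on, sd_s, 1700)
    pp <- multitaper_ffr(tp, attr(tp, "onsets_s"))$ffr_band_power
    pc <- multitaper_ffr(tc, attr(tc, "onsets_s"))$ffr_band_power
    expect_gt(pp, pc)
  }
})

test_that("baseline correction and band bookkeeping are honored", {
  on <- seq(0, 0.5, by = 0.1)
  tr <- make_ieeg_trial(ieeg_trial_spec(ffr_gain = 0, evoked_gain = 0,
                                        seed = 2), on, 0.05, 1700)
  sp <- multitaper_ffr(tr, attr(tr, "onsets_s"))
  expect_equal(length(unique(diff(sp$freq_hz))), 1L)
  expect_true(all(sp$freq_hz >= 0 & sp$freq_hz <= 4800))
  # per-frequency corrected power averages ~0 over the baseline span
  base_mean <- rowMeans(sp$corrected[, sp$baseline_cols])
  expect_lt(max(abs(base_mean)), 1e-9)
  # tapers: 5 orthonormal Slepians
  tp <- vocalrough:::dpss_tapers(480, 3, 5)
  expect_equal(crossprod(tp), diag(5), tolerance = 1e-8)
  # insufficient baseline fails
  expect_error(multitaper_ffr(tr, onsets_s = 0.3), "1.5 s")
})

test_that("evoked averaging obeys the 1/sqrt(N) law", {
  fs <- 9600
  nwin <- round(0.02 * fs)
  tw <- (seq_len(nwin) - 1) / fs
  template <- exp(-tw / 0.004) * sin(2 * pi * 1700 * tw)
  set.seed(5)
  n_on <- 1000
  onsets <- (seq_len(n_on) - 1) * 0.025
  x <- stats::rnorm(round(fs * (n_on * 0.025 + 0.1)))
  for (o in onsets) x[round(o * fs) + seq_len(nwin)] <-
    x[round(o * fs) + seq_len(nwin)] + template
  tr <- waveform(x, fs)
  resid <- vapply(c(10, 100, 1000), function(N) {
    av <- evoked_average(tr, onsets[seq_len(N)])
    sqrt(mean((av$samples - template)^2))
  }, numeric(1))
  # each 10x increase shrinks the residual ~ sqrt(10)
  expect_equal(resid[1] / resid[2], sqrt(10), tolerance = 0.35)
  expect_equal(resid[2] / resid[3], sqrt(10), tolerance = 0.35)
  # single window: the average is that window
  one <- evoked_average(tr, onsets[1])
  expect_equal(one$samples, x[round(onsets[1] * fs) + seq_len(nwin)])
  # windows past the end are dropped with a warning
  expect_warning(evoked_average(tr, c(onsets[1], length(x) / fs - 0.001)),
                 "dropped")
})

test_that("evoked average of a planted FFR peaks near the AM rate", {
  syl <- make_syllable(syllable_spec(am_rate_hz = 1700, am_depth = 0.9,
                                     rate_hz = 192000), seed = 1)
  sq <- make_stimulus_sequence(syl, sequence_layout())
  tr <- make_ieeg_trial(ieeg_trial_spec(ffr_gain = 2, seed = 12),
                        attr(sq, "onsets_s"),
                        attr(sq, "syllable_duration_s"), 1700)
  ev <- evoked_average(tr, attr(tr, "onsets_s"))
  P <- Mod(stats::fft(ev$samples - mean(ev$samples)))^2
  f <- (seq_along(P) - 1) * ev$rate_hz / length(P)
  sel <- f > 200 & f < 4800
  expect_lt(abs(f[sel][which.max(P[sel])] - 1700), 150)
})

test_that("DP amplitudes and noise floors follow the planted truth", {
  sp <- ear_canal_spec(f2_hz = 18000, dp_level_db = 20, seed = 3)
  ep <- make_ear_canal_epochs(sp)
  r <- dp_analysis(ep, sp)
  expect_lt(abs(r$dp_amplitude_db - 20), 1)
  expect_true(r$detected)
  expect_gt(r$dp_amplitude_db - r$noise_floor_db, 20)
  # coherent averaging drops the floor by ~20 dB for 100 epochs
  r1 <- dp_analysis(ep[1, , drop = FALSE], sp)
  expect_lt(abs((r1$noise_floor_db - r$noise_floor_db) - 20), 3)
  # below the cochlear cutoff no DP is planted: amplitude ~ floor
  margins <- vapply(1:20, function(sd) {
    spl <- ear_canal_spec(f2_hz = 1800, seed = sd)
    rl <- dp_analysis(make_ear_canal_epochs(spl), spl)
    rl$dp_amplitude_db - rl$noise_floor_db
  }, numeric(1))
  # the DP bin then holds plain noise: its level sits at the floor on
  # average, with single-bin Rayleigh scatter around it
  expect_lt(abs(stats::median(margins)), 3)
  expect_lte(mean(margins >= 6), 0.15)
})

test_that("DPgram detects the DP exactly above the cochlear cutoff", {
  base <- ear_canal_spec(seed = 41)
  dg <- dp_gram(seq(1000, 25000, by = 1000), base)
  # every planted DP found; chance noise excursions above the 6 dB margin
  # occur at a few percent per point below the cutoff
  expect_true(all(dg$detected[dg$f2_hz >= 5000]))
  expect_lte(sum(dg$detected[dg$f2_hz < 5000]), 1)
  fine <- dp_gram(seq(1000, 3200, by = 200), base)
  expect_lte(sum(fine$detected), 2)
  expect_lt(stats::median(fine$dp_amplitude_db - fine$noise_floor_db), 3)
})
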