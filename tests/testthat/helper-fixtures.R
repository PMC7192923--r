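# Shared fixtures, built once per test run.

# A fast-AM syllable in the default broadband-FM regime.
fix_fam_syllable <- function(rate = 1700, depth = 0.9, dur = 0.005,
                             fs = 300000, seed = 2) {
  make_syllable(syllable_spec(duration_s = dur, am_rate_hz = rate,
                              am_depth = depth, rate_hz = fs), seed = seed)
}

# A quasi-CF syllable whose narrow sweep leaves AM sidebands resolved in
# the spectrum (the spectral-regularity regime).
fix_qcf_regular_syllable <- function(rate = 1600, depth = 0.9,
                                     dur = 0.006, seed = 1) {
  make_syllable(syllable_spec(duration_s = dur,
                              fundamental_start_hz = 21600,
                              fundamental_end_hz = 21200,
                              am_rate_hz = rate, am_depth = depth),
                seed = seed)
}

# Relative modulation depth of a waveform's envelope interior.
env_depth <- function(wave) {
  e <- amplitude_envelope(wave)
  v <- e$values
  i <- seq(max(1L, floor(length(v) * 0.15)),
           ceiling(length(v) * 0.85))
  (max(v[i]) - min(v[i])) / (max(v[i]) + min(v[i]))
}

# Absolute (un-normalized) envelope modulation power in the FOI band.
abs_foi_power <- function(wave) {
  e <- amplitude_envelope(wave)
  v <- e$values - mean(e$values)
  v <- c(v, numeric(round(1 / e$dt_s) - length(v)))
  P <- Mod(stats::fft(v))^2
  f <- (seq_along(P) - 1) / (length(P) * e$dt_s)
  sum(P[f >= 1150 & f <= 2450])
}
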