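# STFT/WOLA identities, MPS geometry, demodulation and synthesis error.

test_that("fixed-parameter STFT concentrates a tone in the right bin", {
  tone <- make_am_tone(20000, 0, 0.05, 192000)
  st <- stft_fixed(tone, pad_to_s = 0.1)
  expect_equal(nrow(st$S), 33L)
  expect_equal(ncol(st$S), round(0.1 * 192000))
  A <- Mod(st$S)
  sig_cols <- st$sig_start:(st$sig_start + st$sig_len - 1L)
  bin_energy <- rowSums(A[, sig_cols]^2)
  # bin spacing 3 kHz: peak bin index for 20 kHz is 20/3 + 1 ~ 8
  expect_equal(which.max(bin_energy), round(20000 / 3000) + 1L)
  # zero signal: all-zero STFT
  expect_equal(max(Mod(stft_fixed(waveform(numeric(100), 192000),
                                  pad_to_s = 0.01)$S)), 0)
  # over-long input fails with advice
  expect_error(stft_fixed(make_am_tone(1000, 0, 0.2, 48000),
                          pad_to_s = 0.1), "pad_to_s")
})

test_that("WOLA inverse is an exact round trip at hop 1", {
  syl <- make_syllable(syllable_spec(am_rate_hz = 1700, am_depth = 0.9,
                                     rate_hz = 192000), seed = 13)
  st <- stft_fixed(syl, pad_to_s = 0.05)
  rec <- istft_wola(st)
  rel <- sqrt(mean((rec$samples - syl$samples)^2)) /
    sqrt(mean(syl$samples^2))
  expect_lt(rel, 1e-6)
  # silence maps to silence
  z <- st; z$S[] <- 0
  expect_equal(max(abs(istft_wola(z)$samples)), 0)
  # linearity: scaling coefficients scales the output
  st2 <- st; st2$S <- st$S * 2
  expect_equal(istft_wola(st2)$samples, rec$samples * 2, tolerance = 1e-12)
  # magnitude-phase recombination identity
  st3 <- st; st3$S <- Mod(st$S) * exp(1i * Arg(st$S))
  expect_lt(sqrt(mean((istft_wola(st3)$samples - syl$samples)^2)) /
              sqrt(mean(syl$samples^2)), 1e-6)
})

test_that("MPS of an AM tone shows side peaks at +/- the AM rate", {
  tone <- make_am_tone(20000, 1700, 0.1, 192000)
  mps <- compute_mps(tone, pad_to_s = 0.2)
  expect_equal(mps_side_peak_hz(mps), 1700, tolerance = 6)
  # the negative-side marginal mirrors it
  m <- mps_temporal_marginal(mps)
  neg <- m$temporal_mod_hz <= -1000 & m$temporal_mod_hz >= -4000
  expect_equal(m$temporal_mod_hz[neg][which.max(m$power[neg])], -1700,
               tolerance = 6)
  # conjugate symmetry of MPS power under joint axis flip
  P <- Mod(mps$Z)^2
  flipped <- P[c(1, nrow(P):2), c(1, ncol(P):2)]
  expect_lt(max(abs(P - flipped)) / max(P), 1e-9)
  expect_error(compute_mps(waveform(numeric(100), 192000)), "zero")
})

test_that("unmodulated tone has no interior side peak in the search band", {
  tone0 <- make_am_tone(20000, 0, 0.1, 192000)
  m0 <- mps_temporal_marginal(compute_mps(tone0, pad_to_s = 0.2))
  sel <- m0$temporal_mod_hz >= 1000 & m0$temporal_mod_hz <= 4000
  # marginal decays away from zero modulation: argmax sits at the band
  # edge, not at an interior AM peak
  edge <- min(m0$temporal_mod_hz[sel])
  expect_lt(m0$temporal_mod_hz[sel][which.max(m0$power[sel])], edge + 100)
  # and the 1.7 kHz cell is orders of magnitude below a true AM peak
  tone1 <- make_am_tone(20000, 1700, 0.1, 192000)
  m1 <- mps_temporal_marginal(compute_mps(tone1, pad_to_s = 0.2))
  at1700 <- function(m) m$power[which.min(abs(m$temporal_mod_hz - 1700))]
  expect_gt(at1700(m1) / at1700(m0), 10)
})

test_that("demodulation strips FOI modulation but preserves the contour", {
  syl <- make_syllable(syllable_spec(am_rate_hz = 1700, am_depth = 0.9,
                                     rate_hz = 192000), seed = 21)
  d <- demodulate(syl, pad_to_s = 0.15)
  expect_lte(d$report$synthesis_error_pct, 2)
  # output RMS matched to input
  expect_equal(sqrt(mean(d$wave$samples^2)), sqrt(mean(syl$samples^2)),
               tolerance = 1e-6)
  # >= 80% of absolute envelope FOI modulation power removed
  expect_lte(abs_foi_power(d$wave) / abs_foi_power(syl), 0.2)
  # downward-FM contour survives
  expect_gte(ridge_correlation(syl, d$wave), 0.95)
  # idempotence within tolerance
  d2 <- demodulate(d$wave, pad_to_s = 0.15)
  expect_gte(spectrogram_correlation(d$wave, d2$wave, pad_to_s = 0.15),
             0.99)
  # energy outside the nullified band moves by <= 5% relative
  marg <- function(w) mps_temporal_marginal(compute_mps(w, pad_to_s = 0.15))
  m_in <- marg(syl); m_out <- marg(d$wave)
  out_band <- abs(m_in$temporal_mod_hz) < 1000 |
    abs(m_in$temporal_mod_hz) > 4000
  expect_lte(abs(sum(m_out$power[out_band]) - sum(m_in$power[out_band])) /
               sum(m_in$power[out_band]), 0.05)
  expect_error(demodulate(syl, band = c(1e6, 2e6)), "band")
})

test_that("demodulating an unmodulated syllable is near-identity", {
  syl0 <- make_syllable(syllable_spec(rate_hz = 192000), seed = 5)
  d0 <- demodulate(syl0, pad_to_s = 0.15)
  expect_gte(spectrogram_correlation(syl0, d0$wave, pad_to_s = 0.15), 0.98)
})

test_that("resynthesis from the unfiltered MPS is error-free", {
  syl <- make_syllable(syllable_spec(am_rate_hz = 1700, am_depth = 0.9,
                                     rate_hz = 192000), seed = 8)
  st <- stft_fixed(syl, pad_to_s = 0.1)
  A <- Mod(st$S)
  eps <- 1e-3 * max(A)
  # log -> 2D FFT -> inverse -> exp with no band nullified
  Z <- stats::fft(log(pmax(A, eps)))
  mag <- pmax(exp(Re(stats::fft(Z, inverse = TRUE)) / length(Z)), eps)
  st2 <- st; st2$S <- mag * exp(1i * Arg(st$S))
  y <- istft_wola(st2)
  obs <- stft_fixed(y, pad_to_s = 0.1)
  expect_lte(synthesis_error(mag, Mod(obs$S)), 0.1)
})

test_that("synthesis error obeys its closed-form identities", {
  m <- matrix(runif(50, 1, 2), 5)
  expect_equal(synthesis_error(m, m), 0)
  expect_equal(synthesis_error(m, 1.01 * m), 0.01, tolerance = 1e-9)
  expect_error(synthesis_error(m, m[, 1:3]), "geometry")
  expect_warning(e <- synthesis_error(m * 0, m), "zero")
  expect_true(is.na(e))
})

test_that("group MPS contrast flags the planted modulation band", {
  mk <- function(am, seed) {
    set.seed(seed)
    tone <- make_am_tone(10000, am, 0.05, 48000)
    tone$samples <- tone$samples + stats::rnorm(length(tone$samples), 0, 0.01)
    compute_mps(tone, pad_to_s = 0.1)
  }
  A <- lapply(1:6, function(i) mk(stats::runif(1, 1600, 1800), i))
  B <- lapply(7:12, function(i) mk(0, i))
  ct <- mps_group_contrast(A, B)
  expect_true(all(abs(ct$delta) <= 1))
  band <- ct$temporal_mod_hz > 1000 & ct$temporal_mod_hz < 2500
  expect_gt(mean(ct$large_mask[, band]), 0.2)
  # identical groups: delta identically zero
  same <- mps_group_contrast(A, A)
  expect_equal(max(abs(same$delta)), 0)
  expect_error(mps_group_contrast(A[1], B), "at least 2")
})
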