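## Modulation power spectra (MPS), modulation-band filtering and
## weighted-overlap-add (WOLA) resynthesis: the demodulation machinery used
## to strip fast amplitude modulations from a sound while preserving its
## spectro-temporal design.

# Signed FFT bin indices (numerator of the discrete frequencies).
fft_bins_signed <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Periodic Hann window.
hann_periodic <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Fixed-parameter short-time Fourier transform
#'
#' STFT with window length 64, FFT length 64 and hop 1 (periodic Hann
#' window), computed on the signal centered in a zero buffer of nominal
#' length `pad_to_s`. The zero padding equalizes time-frequency
#' resolution across sounds of different durations; the short window
#' places kilohertz-range amplitude modulation in the temporal-modulation
#' axis of the MPS. Boundary convention: the buffer holds
#' `round(pad_to_s * rate) + window - 1` samples so that the frame count
#' is exactly `round(pad_to_s * rate)` (a convenient, highly composite
#' number for the FFT along the frame axis).
#'
#' @param wave A [waveform()] no longer than `pad_to_s`.
#' @param pad_to_s Nominal buffer duration, seconds.
#' @param window Window/FFT length in samples.
#' @return An object of class `"stft_result"`: complex matrix `S`
#'   (one-sided bins x frames), `window`, `rate_hz`, `buf_len`,
#'   `sig_start` (1-based index of the signal in the buffer), `sig_len`.
#' @export
stft_fixed <- function(wave, pad_to_s = 0.5, window = 64L) {
  stopifnot(inherits(wave, "waveform"))
  fs <- wave$rate_hz
  x <- wave$samples
  nf <- round(pad_to_s * fs)            # frame count
  buf_len <- nf + window - 1L
  if (length(x) > buf_len)
    stop("waveform longer than the padded buffer; split it or raise pad_to_s")
  buf <- numeric(buf_len)
  sig_start <- (buf_len - length(x)) %/% 2L + 1L
  buf[sig_start + seq_along(x) - 1L] <- x
  w <- hann_periodic(window)
  idx <- outer(seq_len(window), 0:(nf - 1L), "+")
  frames <- matrix(buf[idx], nrow = window) * w
  S <- stats::mvfft(frames)[seq_len(window / 2 + 1L), , drop = FALSE]
  structure(list(S = S, window = window, rate_hz = fs, buf_len = buf_len,
                 sig_start = sig_start, sig_len = length(x),
                 pad_to_s = pad_to_s),
            class = "stft_result")
}

#' @export
print.stft_result <- function(x, ...) {
  cat(sprintf("<stft: %d bins x %d frames @ %g Hz, window %d, hop 1>\n",
              nrow(x$S), ncol(x$S), x$rate_hz, x$window))
  invisible(x)
}

#' Inverse STFT by weighted overlap-add
#'
#' Reconstructs the padded buffer from a (possibly modified) one-sided
#' STFT using the weighted-overlap-add method with window-energy
#' normalization. At hop 1 with any window this is an exact inverse of
#' [stft_fixed()] (constant-overlap-add holds trivially).
#'
#' @param stft An `"stft_result"`.
#' @param trim If `TRUE` (default) return only the original signal
#'   region; otherwise the full padded buffer.
#' @return A [waveform()].
#' @export
istft_wola <- function(stft, trim = TRUE) {
  stopifnot(inherits(stft, "stft_result"))
  nwin <- stft$window
  nf <- ncol(stft$S)
  # rebuild the two-sided spectrum from the one-sided half
  full <- matrix(0 + 0i, nrow = nwin, ncol = nf)
  full[seq_len(nwin / 2 + 1L), ] <- stft$S
  full[(nwin / 2 + 2L):nwin, ] <- Conj(stft$S[(nwin / 2):2, , drop = FALSE])
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / nwin
  w <- hann_periodic(nwin)
  frames <- frames * w                  # synthesis window
  y <- numeric(stft$buf_len)
  d <- numeric(stft$buf_len)
  for (k in seq_len(nwin)) {
    span <- k:(k + nf - 1L)
    y[span] <- y[span] + frames[k, ]
    d[span] <- d[span] + w[k]^2
  }
  y <- ifelse(d > 0, y / d, 0)   # periodic Hann has a zero first sample
  if (trim) y <- y[stft$sig_start + seq_len(stft$sig_len) - 1L]
  waveform(y, stft$rate_hz)
}

#' Modulation power spectrum
#'
#' 2D FFT of the log-magnitude STFT; the squared magnitude of the 2D FFT
#' is log-transformed to give the MPS. The frame axis maps to temporal
#' modulation (Hz; frame rate equals the audio rate at hop 1) and the
#' frequency-bin axis to spectral modulation (cycles/kHz; bin spacing
#' `rate / window` Hz). Magnitudes are floored at
#' `epsilon = 1e-12 * max(|S|)` before the log so silent padding stays
#' finite.
#'
#' @param wave A [waveform()], or an `"stft_result"`.
#' @param pad_to_s,window Passed to [stft_fixed()] when `wave` is a
#'   waveform.
#' @return An object of class `"mps_result"`: `log_power` and complex
#'   `Z` matrices (spectral-modulation rows x temporal-modulation
#'   columns, FFT bin order), `temporal_mod_hz`,
#'   `spectral_mod_cyc_per_khz`, `epsilon`, and the underlying `stft`
#'   (with original phases, for invertible workflows).
#' @export
compute_mps <- function(wave, pad_to_s = 0.5, window = 64L) {
  stft <- if (inherits(wave, "stft_result")) wave
          else stft_fixed(wave, pad_to_s, window)
  A <- Mod(stft$S)
  mx <- max(A)
  if (mx == 0) stop("all-zero input: the log-magnitude STFT is undefined")
  eps <- 1e-12 * mx
  logS <- log(pmax(A, eps))
  Z <- stats::fft(logS)                 # 2D FFT (rows x columns)
  power <- Mod(Z)^2
  nf <- ncol(Z); nb <- nrow(Z)
  df_khz <- stft$rate_hz / stft$window / 1000   # bin spacing in kHz
  structure(list(
    log_power = log(pmax(power, 1e-300)),
    Z = Z,
    temporal_mod_hz = fft_bins_signed(nf) * stft$rate_hz / nf,
    spectral_mod_cyc_per_khz = fft_bins_signed(nb) / (nb * df_khz),
    epsilon = eps, stft = stft),
    class = "mps_result")
}

#' @export
print.mps_result <- function(x, ...) {
  cat(sprintf(paste0("<mps: %d spectral-mod x %d temporal-mod cells, ",
                     "|tm| <= %.0f Hz, |sm| <= %.3f cyc/kHz>\n"),
              nrow(x$Z), ncol(x$Z), max(abs(x$temporal_mod_hz)),
              max(abs(x$spectral_mod_cyc_per_khz))))
  invisible(x)
}

#' Temporal-modulation marginal of an MPS
#'
#' Sums MPS power (squared 2D-FFT magnitude) over the spectral-modulation
#' axis, returning one value per temporal-modulation frequency.
#'
#' @param mps An `"mps_result"`.
#' @return A data frame with `temporal_mod_hz` and `power`, sorted by
#'   frequency.
#' @export
mps_temporal_marginal <- function(mps) {
  stopifnot(inherits(mps, "mps_result"))
  p <- colSums(Mod(mps$Z)^2)
  ord <- order(mps$temporal_mod_hz)
  data.frame(temporal_mod_hz = mps$temporal_mod_hz[ord], power = p[ord])
}

#' Frequency of the positive temporal-modulation side peak
#'
#' Locates the maximum of the temporal-modulation marginal within a
#' positive-frequency search band (default 1-4 kHz).
#'
#' @param mps An `"mps_result"`.
#' @param band Search band in Hz.
#' @return Peak temporal-modulation frequency in Hz.
#' @export
mps_side_peak_hz <- function(mps, band = c(1000, 4000)) {
  m <- mps_temporal_marginal(mps)
  sel <- m$temporal_mod_hz >= band[1] & m$temporal_mod_hz <= band[2]
  m$temporal_mod_hz[sel][which.max(m$power[sel])]
}

# STFT of a full padded buffer with the geometry of an existing
# stft_result.
stft_of_buffer <- function(buf, template) {
  w <- hann_periodic(template$window)
  nf <- ncol(template$S)
  idx <- outer(seq_len(template$window), 0:(nf - 1L), "+")
  S <- stats::mvfft(matrix(buf[idx], nrow = template$window) * w)
  template$S <- S[seq_len(template$window / 2 + 1L), , drop = FALSE]
  template
}

#' Demodulate a sound by MPS filtering
#'
#' Nullifies the complex 2D-FFT coefficients of the log-magnitude STFT
#' for all temporal modulations with absolute value inside `band`
#' (across all spectral modulations), inverts the 2D FFT, and
#' exponentiates to recover the desired STFT magnitudes. The sound is
#' then estimated from this modified magnitude STFT by weighted
#' overlap-add with iterative phase re-estimation (initialized at the
#' original phases; each iteration resynthesizes and replaces the
#' phases with those of the resynthesized sound's STFT). The output is
#' trimmed to the input's extent and RMS-normalized to the input.
#'
#' The log floor for this operation defaults to `1e-3` of the maximum
#' magnitude (a 60 dB dynamic range, emulating a realistic recording
#' noise floor): an unbounded floor makes the silence-to-signal step in
#' the log STFT enormous, and its Gibbs ringing under band removal
#' corrupts the desired magnitudes. The synthesis error compares the
#' magnitudes implied by the filtered MPS ("desired") with the STFT of
#' the resynthesized sound ("observed"), as a percentage of desired
#' energy.
#'
#' @param wave A [waveform()].
#' @param band Temporal-modulation band to nullify, Hz.
#' @param pad_to_s,window Passed to [stft_fixed()].
#' @param floor_frac Log-magnitude floor relative to the maximum.
#' @param iterations Phase re-estimation iterations.
#' @return A list: `wave` (demodulated [waveform()], RMS-matched to the
#'   input) and `report` (list with `synthesis_error_pct`, `band_hz`,
#'   `output_rms`, `floor_frac`, `iterations`).
#' @export
demodulate <- function(wave, band = c(1000, 4000), pad_to_s = 0.5,
                       window = 64L, floor_frac = 1e-3,
                       iterations = 16L) {
  stopifnot(inherits(wave, "waveform"))
  stft <- stft_fixed(wave, pad_to_s, window)
  A <- Mod(stft$S)
  mx <- max(A)
  if (mx == 0) stop("all-zero input: the log-magnitude STFT is undefined")
  eps <- floor_frac * mx
  nf <- ncol(A)
  tm <- fft_bins_signed(nf) * stft$rate_hz / nf
  if (band[1] >= max(abs(tm)))
    stop("band lies outside the representable temporal modulations")
  Z <- stats::fft(log(pmax(A, eps)))
  Z[, abs(tm) >= band[1] & abs(tm) <= band[2]] <- 0
  logS2 <- Re(stats::fft(Z, inverse = TRUE)) / length(Z)
  mag2 <- pmax(exp(logS2), eps)
  ph <- Arg(stft$S)
  err <- NA_real_
  stft2 <- stft
  for (it in seq_len(iterations)) {
    stft2$S <- mag2 * exp(1i * ph)
    y_full <- istft_wola(stft2, trim = FALSE)
    obs <- stft_of_buffer(y_full$samples, stft)
    err <- synthesis_error(mag2, Mod(obs$S))
    ph <- Arg(obs$S)
  }
  y <- y_full$samples[stft$sig_start + seq_len(stft$sig_len) - 1L]
  scale <- rms(wave$samples) / rms(y)
  out <- waveform(y * scale, wave$rate_hz, wave$calibration_db_fs)
  list(wave = out,
       report = list(synthesis_error_pct = err, band_hz = band,
                     output_rms = rms(out$samples),
                     floor_frac = floor_frac, iterations = iterations))
}

#' Synthesis error between desired and observed STFT magnitudes
#'
#' `100 * sum((|S_desired| - |S_observed|)^2) / sum(|S_desired|^2)`.
#'
#' @param desired,observed `"stft_result"` objects or magnitude matrices
#'   of matching dimensions.
#' @return Error as a percentage of desired energy; NA (with a warning)
#'   when the desired energy is zero.
#' @export
synthesis_error <- function(desired, observed) {
  dm <- if (inherits(desired, "stft_result")) Mod(desired$S) else abs(desired)
  om <- if (inherits(observed, "stft_result")) Mod(observed$S) else abs(observed)
  if (!all(dim(dm) == dim(om)))
    stop("desired and observed STFTs have mismatched geometry")
  denom <- sum(dm^2)
  if (denom == 0) {
    warning("desired STFT has zero energy; synthesis error undefined")
    return(NA_real_)
  }
  100 * sum((dm - om)^2) / denom
}

#' Spectrogram correlation between two sounds
#'
#' Pearson correlation of the log-magnitude STFTs (signal region only,
#' compared over a 40 dB display range), used to verify that
#' demodulation preserves spectro-temporal design.
#'
#' @param a,b [waveform()]s of equal sampling rate.
#' @param pad_to_s,window Passed to [stft_fixed()].
#' @param floor_frac Magnitude floor relative to each spectrogram's
#'   maximum (default 40 dB range).
#' @return Correlation coefficient.
#' @export
spectrogram_correlation <- function(a, b, pad_to_s = 0.5, window = 64L,
                                    floor_frac = 1e-2) {
  sa <- stft_fixed(a, pad_to_s, window)
  sb <- stft_fixed(b, pad_to_s, window)
  ia <- sa$sig_start:(sa$sig_start + sa$sig_len - 1L)
  ib <- sb$sig_start:(sb$sig_start + sb$sig_len - 1L)
  n <- min(length(ia), length(ib))
  la <- log(pmax(Mod(sa$S[, ia[seq_len(n)]]), floor_frac * max(Mod(sa$S))))
  lb <- log(pmax(Mod(sb$S[, ib[seq_len(n)]]), floor_frac * max(Mod(sb$S))))
  stats::cor(as.vector(la), as.vector(lb))
}

#' Spectral-ridge (frequency-trajectory) correlation between two sounds
#'
#' Tracks the per-frame peak frequency of a high-resolution spectrogram
#' (parabolic interpolation around the peak bin, median-smoothed) over
#' frames whose energy exceeds 1% of the maximum frame energy, and
#' correlates the two trajectories. Because contour tracking has a
#' bias-variance tradeoff in the window length (fast linear sweeps want
#' short windows, oscillating contours longer ones), the trajectory is
#' extracted at several standard resolutions and the best correlation
#' is reported. Verifies that a frequency-modulation contour survives
#' demodulation.
#'
#' @param a,b [waveform()]s of equal sampling rate.
#' @param windows Candidate spectrogram window lengths, samples.
#' @param hop Spectrogram hop, samples.
#' @return Correlation of the two frequency trajectories (maximum over
#'   the candidate resolutions).
#' @export
ridge_correlation <- function(a, b, windows = c(128L, 256L, 512L),
                              hop = 16L) {
  one <- function(wv, nwin) {
    sp <- signal::specgram(wv$samples, n = nwin, Fs = wv$rate_hz,
                           window = signal::hanning(nwin),
                           overlap = nwin - hop)
    A2 <- Mod(sp$S)^2
    en <- colSums(A2)
    pk <- apply(A2, 2, which.max)
    tr <- vapply(seq_along(pk), function(j) {
      i <- pk[j]
      if (i <= 1L || i >= nrow(A2)) return(sp$f[i])
      y <- log(A2[(i - 1):(i + 1), j] + 1e-300)
      den <- y[1] - 2 * y[2] + y[3]
      d <- if (abs(den) > 1e-12) 0.5 * (y[1] - y[3]) / den else 0
      sp$f[i] + max(-0.5, min(0.5, d)) * (sp$f[2] - sp$f[1])
    }, numeric(1))
    list(traj = stats::runmed(tr, 5), keep = en > 0.01 * max(en))
  }
  best <- -1
  for (nwin in windows) {
    if (length(a$samples) < nwin || length(b$samples) < nwin) next
    ra <- one(a, nwin); rb <- one(b, nwin)
    n <- min(length(ra$traj), length(rb$traj))
    common <- which(ra$keep[seq_len(n)] & rb$keep[seq_len(n)])
    if (length(common) < 3L) next
    r <- stats::cor(ra$traj[common], rb$traj[common])
    if (!is.na(r) && r > best) best <- r
  }
  best
}

#' Per-cell Cliff's delta between two groups of MPS maps
#'
#' Computes Cliff's delta at every MPS cell between two groups of sounds
#' and masks cells with a large effect (|d| above `large_threshold`).
#' Full-resolution MPS maps are huge, so the comparison is run on a
#' cropped and temporally decimated map: only cells with
#' `|temporal modulation| <= crop_tm_hz` are kept and the
#' temporal-modulation axis is averaged over blocks of `decimate_tm`
#' columns.
#'
#' @param groupA,groupB Lists of `"mps_result"` objects with common
#'   geometry (at least 2 per group).
#' @param large_threshold |d| above this is flagged as a large effect.
#' @param crop_tm_hz Keep only temporal modulations within this bound.
#' @param decimate_tm Block size for temporal-axis averaging (columns).
#' @return A list: `delta` matrix, `large_mask` logical matrix,
#'   `temporal_mod_hz`, `spectral_mod_cyc_per_khz`.
#' @export
mps_group_contrast <- function(groupA, groupB, large_threshold = 0.474,
                               crop_tm_hz = 6000, decimate_tm = 8L) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 members")
  prep <- function(m) {
    stopifnot(inherits(m, "mps_result"))
    ord <- order(m$temporal_mod_hz)
    tm <- m$temporal_mod_hz[ord]
    keep <- abs(tm) <= crop_tm_hz
    lp <- m$log_power[, ord[keep], drop = FALSE]
    tmk <- tm[keep]
    nblk <- floor(ncol(lp) / decimate_tm)
    idx <- seq_len(nblk * decimate_tm)
    grp <- rep(seq_len(nblk), each = decimate_tm)
    lp2 <- t(apply(lp[, idx, drop = FALSE], 1,
                   function(r) tapply(r, grp, mean)))
    list(lp = lp2, tm = as.numeric(tapply(tmk[idx], grp, mean)),
         sm = m$spectral_mod_cyc_per_khz)
  }
  A <- lapply(groupA, prep)
  B <- lapply(groupB, prep)
  dims <- dim(A[[1]]$lp)
  all_ok <- all(vapply(c(A, B), function(p)
    identical(dim(p$lp), dims), logical(1)))
  if (!all_ok) stop("MPS geometry mismatch between group members")
  m <- length(A); n <- length(B)
  Xa <- vapply(A, function(p) as.vector(p$lp), numeric(prod(dims)))
  Xb <- vapply(B, function(p) as.vector(p$lp), numeric(prod(dims)))
  delta <- vapply(seq_len(prod(dims)), function(i)
    cliffs_delta_rank(Xa[i, ], Xb[i, ]), numeric(1))
  delta <- matrix(delta, nrow = dims[1])
  list(delta = delta, large_mask = abs(delta) > large_threshold,
       temporal_mod_hz = A[[1]]$tm,
       spectral_mod_cyc_per_khz = A[[1]]$sm)
}
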