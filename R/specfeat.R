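## Per-syllable acoustic features: amplitude envelope, temporal modulation
## spectrum (TMS), 200-Hz-resolution spectrum, harmonic-to-noise difference,
## spectral autocorrelogram and band sound pressure levels.

# Frequency band (Hz) used for roughness quantification: the
# "frequencies of interest" of the temporal modulation spectrum.
FOI_BAND_HZ <- c(1150, 2450)

# Analytic-signal magnitude via the FFT Hilbert transform.
analytic_magnitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Zero-phase brickwall low-pass via FFT.
fft_lowpass <- function(x, fs, cutoff_hz) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f > cutoff_hz] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Amplitude envelope of a syllable
#'
#' Magnitude of the analytic signal, low-pass filtered below the envelope
#' Nyquist frequency `1 / (2 * dt_s)` and resampled onto the `dt_s` grid.
#'
#' @param syllable A [waveform()].
#' @param dt_s Envelope sampling interval, seconds (default 0.1 ms).
#' @return An object of class `"envelope_series"`: list with `values`
#'   (non-negative amplitudes) and `dt_s`.
#' @export
amplitude_envelope <- function(syllable, dt_s = 1e-4) {
  stopifnot(inherits(syllable, "waveform"))
  x <- syllable$samples
  if (!length(x)) stop("empty input")
  fs <- syllable$rate_hz
  if (length(x) / fs < 2 * dt_s)
    stop("syllable shorter than two envelope samples")
  env <- analytic_magnitude(x)
  env <- fft_lowpass(env, fs, 1 / (2 * dt_s))
  t_in <- (seq_along(env) - 1) / fs
  t_out <- seq(0, max(t_in), by = dt_s)
  vals <- stats::approx(t_in, env, xout = t_out)$y
  structure(list(values = pmax(vals, 0), dt_s = dt_s),
            class = "envelope_series")
}

# Relative modulation depth (max - min) / (max + min) over the interior
# of an envelope (edge fraction trimmed to avoid onset/offset ramps).
modulation_depth <- function(env, trim_frac = 0.15) {
  v <- env$values
  n <- length(v)
  i <- seq(max(1L, floor(n * trim_frac)), ceiling(n * (1 - trim_frac)))
  v <- v[i]
  (max(v) - min(v)) / (max(v) + min(v))
}

#' Temporal modulation spectrum of an amplitude envelope
#'
#' The mean-subtracted envelope is zero-padded to 1 s (fixing the grid
#' resolution at 1 Hz regardless of syllable duration) and
#' Fourier-transformed; the squared magnitude on the 0-4 kHz grid is
#' normalized to unit total power. The best modulation frequency (BMF) is
#' the argmax within the 1.15-2.45 kHz frequencies of interest (FOI), and
#' `foi_area` the trapezoidal area of the normalized power over the FOI.
#'
#' @param env An `"envelope_series"` from [amplitude_envelope()].
#' @param fmax_hz Upper edge of the TMS grid, Hz.
#' @return An object of class `"tms"`: list with `freq_hz`, `power`
#'   (sums to 1 over the grid for non-degenerate input), `bmf_hz`
#'   (NA when the envelope is constant), `foi_area`, and `degenerate`
#'   flag.
#' @export
temporal_modulation_spectrum <- function(env, fmax_hz = 4000) {
  stopifnot(inherits(env, "envelope_series"))
  v <- env$values - mean(env$values)
  n_pad <- round(1 / env$dt_s)          # 1 s of envelope samples
  v <- c(v, numeric(n_pad - length(v)))
  P <- Mod(stats::fft(v))^2
  freq <- (seq_len(n_pad) - 1) / (n_pad * env$dt_s)
  keep <- freq <= fmax_hz
  freq <- freq[keep]; P <- P[keep]
  tot <- sum(P)
  if (tot <= .Machine$double.eps * length(P)) {
    return(structure(list(freq_hz = freq, power = P * 0, bmf_hz = NA_real_,
                          foi_area = 0, degenerate = TRUE), class = "tms"))
  }
  P <- P / tot
  foi <- freq >= FOI_BAND_HZ[1] & freq <= FOI_BAND_HZ[2]
  bmf <- freq[foi][which.max(P[foi])]
  structure(list(freq_hz = freq, power = P, bmf_hz = bmf,
                 foi_area = trapz(freq[foi], P[foi]), degenerate = FALSE),
            class = "tms")
}

#' @export
print.tms <- function(x, ...) {
  cat(sprintf("<tms: %d bins 0-%g Hz, BMF %s Hz, FOI area %.4g%s>\n",
              length(x$freq_hz), max(x$freq_hz),
              if (is.na(x$bmf_hz)) "NA" else format(x$bmf_hz),
              x$foi_area, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Moving average with shrinking windows at the edges.
moving_average <- function(x, half_width = 2L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - half_width):min(n, i + half_width)
    mean(x[j])
  }, numeric(1))
}

#' 200-Hz-resolution power spectrum and harmonic-to-noise difference
#'
#' The magnitude FFT of the syllable is linearly interpolated onto a
#' fixed 200 Hz grid (making spectra of different-length syllables
#' comparable), peak-normalized, and summarized by its peak frequency,
#' spectral area (trapezoidal area of the normalized spectrum, in kHz of
#' equivalent full-power bandwidth) and the harmonic-to-noise difference
#' (HND): the maximum absolute difference between the normalized spectrum
#' and its 5-point moving average (shrinking windows at the edges).
#'
#' @param syllable A [waveform()].
#' @param step_hz Grid resolution, Hz.
#' @return An object of class `"power_spectrum_200"`: `freq_hz`,
#'   `magnitude`, `normalized` (peak = 1), `peak_frequency_hz`,
#'   `spectral_area_khz`, `hnd`.
#' @export
power_spectrum_200hz <- function(syllable, step_hz = 200) {
  stopifnot(inherits(syllable, "waveform"))
  x <- syllable$samples
  if (!length(x)) stop("empty input")
  fs <- syllable$rate_hz
  n <- length(x)
  X <- Mod(stats::fft(x))
  f_native <- (seq_len(n) - 1) * fs / n
  keep <- f_native <= fs / 2
  grid <- seq(0, fs / 2, by = step_hz)
  mag <- stats::approx(f_native[keep], X[keep], xout = grid, rule = 2)$y
  norm <- mag / max(mag)
  smooth <- moving_average(norm, 2L)
  structure(list(freq_hz = grid, magnitude = mag, normalized = norm,
                 peak_frequency_hz = grid[which.max(norm)],
                 spectral_area_khz = trapz(grid / 1000, norm),
                 hnd = max(abs(norm - smooth))),
            class = "power_spectrum_200")
}

# Local maxima of y with topographic prominence >= prom.
find_peaks_prominence <- function(y, prom) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  keep <- vapply(is_max, function(i) {
    h <- y[i]
    # walk left until a higher point (or the edge); base = min on the way
    left <- i - 1L; lmin <- h
    while (left >= 1L && y[left] <= h) { lmin <- min(lmin, y[left]); left <- left - 1L }
    right <- i + 1L; rmin <- h
    while (right <= n && y[right] <= h) { rmin <- min(rmin, y[right]); right <- right + 1L }
    (h - max(lmin, rmin)) >= prom
  }, logical(1))
  is_max[keep]
}

#' Spectral autocorrelogram and median inter-peak distance
#'
#' Normalized autocovariance of the mean-subtracted normalized spectrum
#' over lags up to +/-10 kHz. Local maxima on positive lags (excluding
#' lag 0) are detected at the given topographic prominence; the median
#' inter-peak distance (MIPD) measures spectral sideband regularity and
#' is undefined (NA, flagged) when fewer than two peaks are found.
#'
#' @param spec A `"power_spectrum_200"` from [power_spectrum_200hz()].
#' @param prominence Minimum peak prominence on the correlation scale.
#' @param max_lag_hz Maximum lag, Hz.
#' @param summary Either `"median"` (default) or `"mean"` inter-peak
#'   distance.
#' @return An object of class `"spectral_autocorrelogram"`: `lag_hz`
#'   (symmetric grid), `corr` (lag 0 = 1), `peak_lags_hz`, `mipd_hz`,
#'   `defined` flag.
#' @export
spectral_autocorrelogram <- function(spec, prominence = 0.025,
                                     max_lag_hz = 10000,
                                     summary = c("median", "mean")) {
  stopifnot(inherits(spec, "power_spectrum_200"))
  summary <- match.arg(summary)
  step <- spec$freq_hz[2] - spec$freq_hz[1]
  v <- spec$normalized - mean(spec$normalized)
  n <- length(v)
  max_lag <- min(n - 1L, round(max_lag_hz / step))
  ac <- vapply(0:max_lag, function(k)
    sum(v[1:(n - k)] * v[(1 + k):n]), numeric(1))
  ac <- ac / ac[1]
  lag_hz <- c(rev(-seq_len(max_lag)), 0, seq_len(max_lag)) * step
  corr <- c(rev(ac[-1]), ac)
  pk <- find_peaks_prominence(ac, prominence)   # indices into 0..max_lag (+1)
  peak_lags <- (pk - 1L) * step
  peak_lags <- peak_lags[peak_lags > 0]
  mipd <- if (length(peak_lags) >= 2L) {
    d <- diff(sort(peak_lags))
    if (summary == "median") stats::median(d) else mean(d)
  } else NA_real_
  structure(list(lag_hz = lag_hz, corr = corr, peak_lags_hz = peak_lags,
                 mipd_hz = mipd, defined = !is.na(mipd)),
            class = "spectral_autocorrelogram")
}

#' Band sound pressure level of a calibrated waveform
#'
#' Applies a single-pass 3rd-order Butterworth bandpass and expresses the
#' RMS of the filtered signal in dB SPL by comparison with the RMS that a
#' 94 dB SPL calibrator tone would have under the waveform's full-scale
#' calibration.
#'
#' @param syllable A [waveform()] with a calibration, or pass
#'   `calibration_db_fs` explicitly.
#' @param band Numeric length-2: band edges in Hz (`low < high <
#'   rate / 2`).
#' @param calibration_db_fs dB SPL of a full-scale RMS sinusoid.
#' @return A list with `band_hz` and `level_db_spl`.
#' @export
band_spl <- function(syllable, band, calibration_db_fs = NULL) {
  stopifnot(inherits(syllable, "waveform"))
  cal <- if (!is.null(calibration_db_fs)) calibration_db_fs
         else syllable$calibration_db_fs
  if (is.null(cal))
    stop("band_spl requires a calibration (dB SPL at full scale); ",
         "set calibration_db_fs")
  fs <- syllable$rate_hz
  if (!(band[1] < band[2] && band[2] < fs / 2))
    stop("band must satisfy low < high < rate/2")
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  y <- signal::filter(bf, syllable$samples)
  # RMS of the 94 dB SPL calibrator under this calibration: a full-scale
  # sine (RMS 1/sqrt(2)) corresponds to `cal` dB SPL.
  rms_ref <- (1 / sqrt(2)) * 10^((94 - cal) / 20)
  list(band_hz = band,
       level_db_spl = 20 * log10(rms(as.numeric(y)) / rms_ref) + 94)
}

#' Carrier-to-modulator frequency ratio
#'
#' @param peak_frequency_hz Peak (carrier) frequency, Hz.
#' @param bmf_hz Best modulation frequency, Hz (NA when undefined).
#' @return The ratio `peak_frequency_hz / bmf_hz`, or NA when `bmf_hz`
#'   is undefined or non-positive.
#' @export
carrier_modulator_ratio <- function(peak_frequency_hz, bmf_hz) {
  ifelse(is.na(bmf_hz) | bmf_hz <= 0, NA_real_, peak_frequency_hz / bmf_hz)
}

#' Full feature set for one syllable
#'
#' Convenience wrapper computing all per-syllable features.
#'
#' @param syllable A [waveform()].
#' @param calibration_db_fs Optional calibration for band levels.
#' @return A one-row data frame: duration_s, bmf_hz, foi_area,
#'   peak_frequency_hz, spectral_area_khz, hnd, mipd_hz,
#'   carrier_modulator_ratio, and (when calibrated) band_spl_foi /
#'   band_spl_20k.
#' @export
syllable_features <- function(syllable, calibration_db_fs = NULL) {
  env <- amplitude_envelope(syllable)
  tms <- temporal_modulation_spectrum(env)
  ps <- power_spectrum_200hz(syllable)
  ac <- spectral_autocorrelogram(ps)
  out <- data.frame(
    duration_s = wave_duration(syllable),
    bmf_hz = tms$bmf_hz, foi_area = tms$foi_area,
    peak_frequency_hz = ps$peak_frequency_hz,
    spectral_area_khz = ps$spectral_area_khz, hnd = ps$hnd,
    mipd_hz = ac$mipd_hz,
    carrier_modulator_ratio =
      carrier_modulator_ratio(ps$peak_frequency_hz, tms$bmf_hz))
  cal <- if (!is.null(calibration_db_fs)) calibration_db_fs
         else syllable$calibration_db_fs
  if (!is.null(cal)) {
    out$band_spl_foi <- band_spl(syllable, FOI_BAND_HZ, cal)$level_db_spl
    out$band_spl_20k <- band_spl(syllable, c(20000, 21300), cal)$level_db_spl
  }
  out
}
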