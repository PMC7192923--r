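## Physiological response quantification: QRS detection and heart-rate
## response areas (ECG), multitaper frequency-following-response analysis
## (iEEG), and distortion-product otoacoustic emission amplitudes
## (ear-canal epochs).

#' Detect QRS complexes by amplitude threshold
#'
#' Events are local maxima of the smoothed signal envelope (rectified
#' signal averaged over `smooth_s`) exceeding a detection threshold,
#' separated by at least `refractory_s`. The threshold is at least
#' `k_sd` times the noise SD of the envelope — estimated robustly
#' (1.4826 x median after a two-pass exclusion of provisional spikes) —
#' and additionally at least `rel_frac` of the robust spike amplitude
#' (the envelope's 99.9th percentile), which suppresses chance noise
#' excursions above the bare `k_sd` floor on long traces. The dominant
#' deflection polarity is reported alongside.
#'
#' @param ecg A [waveform()].
#' @param k_sd Noise-SD multiple forming the threshold floor.
#' @param refractory_s Minimum separation between events, seconds.
#' @param smooth_s Envelope smoothing window, seconds.
#' @param rel_frac Fraction of the robust spike amplitude also required.
#' @return An object of class `"qrs_series"`: `times_s` (strictly
#'   increasing), `threshold`, `polarity`, `noise_sd`.
#' @export
detect_qrs <- function(ecg, k_sd = 2, refractory_s = 0.020,
                       smooth_s = 0.001, rel_frac = 0.3) {
  stopifnot(inherits(ecg, "waveform"))
  x <- ecg$samples
  if (!length(x)) stop("empty ECG trace")
  fs <- ecg$rate_hz
  polarity <- if (max(x) >= -min(x)) 1 else -1
  w <- max(1L, round(smooth_s * fs))
  env <- abs(x)
  if (w > 1L) {
    env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
    env[is.na(env)] <- 0
  }
  # two-pass robust noise SD of the envelope
  sd0 <- 1.4826 * stats::median(env)
  kept <- if (sd0 > 0) env <= 4 * sd0 else rep(TRUE, length(env))
  noise_sd <- 1.4826 * stats::median(env[kept])
  empty <- structure(list(times_s = numeric(0), threshold = NA_real_,
                          polarity = polarity, noise_sd = noise_sd),
                     class = "qrs_series")
  if (noise_sd == 0) return(empty)
  spike_amp <- stats::quantile(env, 0.999, names = FALSE)
  thresh <- max(k_sd * noise_sd, rel_frac * spike_amp)
  s <- env
  n <- length(s)
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n] &
                  s[2:(n - 1)] > thresh) + 1L
  if (!length(cand)) return(empty)
  # refractory: keep the larger of any two candidates closer than
  # refractory_s
  refr <- round(refractory_s * fs)
  keep <- logical(length(cand))
  last <- -Inf; last_i <- 0L
  for (j in seq_along(cand)) {
    if (cand[j] - last >= refr) {
      keep[j] <- TRUE; last <- cand[j]; last_i <- j
    } else if (s[cand[j]] > s[cand[last_i]]) {
      keep[last_i] <- FALSE; keep[j] <- TRUE
      last <- cand[j]; last_i <- j
    }
  }
  structure(list(times_s = (cand[keep] - 1L) / fs, threshold = thresh,
                 polarity = polarity, noise_sd = noise_sd),
            class = "qrs_series")
}

#' @export
print.qrs_series <- function(x, ...) {
  cat(sprintf("<qrs_series: %d events, polarity %+d, threshold %.3g>\n",
              length(x$times_s), x$polarity, x$threshold))
  invisible(x)
}

#' Instantaneous heart-rate curve and response area
#'
#' Instantaneous HR is 60 divided by the interval between consecutive
#' QRS events (beats per minute), assigned at the later beat of each
#' pair, then linearly interpolated onto a 0.5-s grid from `-pre_s` to
#' `+post_s` relative to stimulus onset. A trial is invalid when any
#' instantaneous HR exceeds `artifact_hr_bpm` (960 bpm, i.e. an
#' inter-beat interval of 62 ms or shorter), the movement-artifact
#' signature. The response area is the
#' trapezoidal area of the baseline-subtracted curve over the first
#' `post_s` seconds (baseline = mean over `[-pre_s, 0)`).
#'
#' @param qrs A `"qrs_series"` with at least 2 events.
#' @param stimulus_onset_s Stimulus onset, seconds.
#' @param pre_s,post_s Curve extent around onset, seconds.
#' @param grid_step_s Interpolation resolution, seconds.
#' @param artifact_hr_bpm Instantaneous rates above this invalidate
#'   the trial.
#' @param baseline_subtract If `FALSE`, the raw (non-baseline-subtracted)
#'   area is reported.
#' @return An object of class `"hr_curve"`: `time_s` (relative grid),
#'   `bpm`, `valid`, `baseline_bpm`, `response_area` (bpm*s).
#' @export
hr_curve <- function(qrs, stimulus_onset_s, pre_s = 5, post_s = 10,
                     grid_step_s = 0.5, artifact_hr_bpm = 960,
                     baseline_subtract = TRUE) {
  stopifnot(inherits(qrs, "qrs_series"))
  tt <- qrs$times_s
  if (length(tt) < 2L)
    return(structure(list(time_s = numeric(0), bpm = numeric(0),
                          valid = FALSE, baseline_bpm = NA_real_,
                          response_area = NA_real_), class = "hr_curve"))
  iv <- diff(tt)
  hr <- 60 / iv
  hr_t <- tt[-1L]                        # assigned at the later beat
  valid <- !any(hr > artifact_hr_bpm)
  grid <- seq(-pre_s, post_s, by = grid_step_s)
  bpm <- if (length(hr) >= 2L)
    stats::approx(hr_t - stimulus_onset_s, hr, xout = grid, rule = 2)$y
  else rep(hr, length(grid))
  base <- mean(bpm[grid >= -pre_s & grid < 0])
  post <- grid >= 0
  area <- trapz(grid[post],
                bpm[post] - if (baseline_subtract) base else 0)
  structure(list(time_s = grid, bpm = bpm, valid = valid,
                 baseline_bpm = base, response_area = area),
            class = "hr_curve")
}

#' Summarize heart-rate response areas by animal and condition
#'
#' Averages response areas over valid trials per animal and condition,
#' z-scores the condition means within each animal, and runs a two-sided
#' paired signed-rank test across animals on the raw per-animal means of
#' two conditions.
#'
#' @param trials A data frame with columns `animal`, `condition`,
#'   `area`, `valid`.
#' @param test_pair Length-2 character: the two conditions to compare
#'   (defaults to the first two condition levels).
#' @return A list: `per_animal` (data frame of per-animal means and
#'   z-scores), `p` (paired signed-rank, NA when fewer than two animals
#'   have both conditions), `test_pair`, `n_animals`.
#' @export
hr_condition_summary <- function(trials, test_pair = NULL) {
  stopifnot(all(c("animal", "condition", "area", "valid") %in%
                  names(trials)))
  tv <- trials[trials$valid & !is.na(trials$area), ]
  agg <- stats::aggregate(area ~ animal + condition, tv, mean)
  # warn for animal x condition cells with no valid trials
  full <- expand.grid(animal = unique(trials$animal),
                      condition = unique(trials$condition))
  have <- paste(agg$animal, agg$condition)
  missing <- full[!paste(full$animal, full$condition) %in% have, ]
  if (nrow(missing))
    warning("no valid trials for: ",
            paste(missing$animal, missing$condition, collapse = "; "))
  agg$z <- stats::ave(agg$area, agg$animal, FUN = function(v)
    if (length(v) > 1L && stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
    else v * 0)
  conds <- unique(as.character(agg$condition))
  if (is.null(test_pair)) test_pair <- conds[seq_len(min(2L, length(conds)))]
  p <- NA_real_
  if (length(test_pair) == 2L) {
    a <- agg[agg$condition == test_pair[1], c("animal", "area")]
    b <- agg[agg$condition == test_pair[2], c("animal", "area")]
    m <- merge(a, b, by = "animal")
    if (nrow(m) >= 2L && !all(m$area.x == m$area.y))
      p <- paired_and_unpaired_tests(m$area.x, m$area.y, paired = TRUE)$p
  }
  list(per_animal = agg, p = p, test_pair = test_pair,
       n_animals = length(unique(agg$animal)))
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal formulation; returns an n x k matrix of unit-norm tapers.
dpss_tapers <- function(n, nw = 3, k = 5L) {
  w <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  m <- diag(d)
  m[cbind(seq_len(n - 1), 2:n)] <- e
  m[cbind(2:n, seq_len(n - 1))] <- e
  ev <- eigen(m, symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  # fix sign convention: make each taper's mean (or first lobe) positive
  for (j in seq_len(k)) if (sum(v[, j]) < 0 ||
                            (abs(sum(v[, j])) < 1e-12 && v[2, j] < 0))
    v[, j] <- -v[, j]
  v
}

#' Multitaper spectrogram and frequency-following-response band power
#'
#' Multitaper (5 DPSS tapers, time-bandwidth product 3) sliding-window
#' spectrogram of an iEEG trace, baseline-corrected by subtracting the
#' mean power at each frequency over the stimulus-free baseline (the
#' span before the first onset, which must be at least 1.5 s). The FFR
#' band power is the mean corrected power within `band` over the
#' stimulus extent.
#'
#' @param ieeg A [waveform()].
#' @param onsets_s Stimulus syllable onsets within the trace, seconds.
#' @param band FFR band, Hz.
#' @param window_s,step_s Spectrogram window and step, seconds.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @param stimulus_end_s End of the stimulus extent; defaults to the
#'   last onset plus the median onset spacing.
#' @return An object of class `"neural_spectrogram"`: `time_s` (window
#'   centers), `freq_hz`, `power`, `corrected`, `ffr_band_power`,
#'   `band_hz`.
#' @export
multitaper_ffr <- function(ieeg, onsets_s, band = c(1600, 2000),
                           window_s = 0.050, step_s = 0.005, nw = 3,
                           k = 5L, stimulus_end_s = NULL) {
  stopifnot(inherits(ieeg, "waveform"))
  fs <- ieeg$rate_hz
  first_onset <- min(onsets_s)
  if (first_onset < 1.5)
    stop("at least 1.5 s of stimulus-free baseline is required before ",
         "the first onset (got ", round(first_onset, 3), " s)")
  if (is.null(stimulus_end_s))
    stimulus_end_s <- max(onsets_s) +
      if (length(onsets_s) > 1L) stats::median(diff(sort(onsets_s))) else
        window_s
  x <- ieeg$samples
  nwin <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  tapers <- dpss_tapers(nwin, nw, k)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  nb <- nwin %/% 2L + 1L
  power <- matrix(0, nrow = nb, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j] + 0:(nwin - 1L)]
    tp <- stats::mvfft(tapers * seg)
    power[, j] <- rowMeans(Mod(tp[seq_len(nb), , drop = FALSE])^2)
  }
  centers <- (starts - 1L + nwin / 2) / fs
  freq <- (seq_len(nb) - 1) * fs / nwin
  base_cols <- (starts - 1L) / fs >= 0 &
    (starts - 1L + nwin) / fs <= first_onset
  if (!any(base_cols)) stop("no spectrogram windows fall in the baseline")
  corrected <- power - rowMeans(power[, base_cols, drop = FALSE])
  stim_cols <- centers >= first_onset & centers <= stimulus_end_s
  brows <- freq >= band[1] & freq <= band[2]
  ffr <- mean(corrected[brows, stim_cols, drop = FALSE])
  structure(list(time_s = centers, freq_hz = freq, power = power,
                 corrected = corrected, ffr_band_power = ffr,
                 band_hz = band, baseline_cols = base_cols,
                 stimulus_cols = stim_cols),
            class = "neural_spectrogram")
}

#' Stimulus-locked evoked average
#'
#' Averages fixed-length windows starting at each syllable onset, across
#' onsets (and across trials when a list of traces is supplied). Windows
#' running past the end of a trace are dropped with a warning.
#'
#' @param ieeg A [waveform()] or list of them.
#' @param onsets_s Onset vector, or list of vectors matching `ieeg`.
#' @param window_s Averaging window, seconds.
#' @return A [waveform()] holding the average; attribute `n_windows`.
#' @export
evoked_average <- function(ieeg, onsets_s, window_s = 0.020) {
  traces <- if (inherits(ieeg, "waveform")) list(ieeg) else ieeg
  onset_list <- if (is.list(onsets_s)) onsets_s else list(onsets_s)
  stopifnot(length(traces) == length(onset_list))
  fs <- traces[[1]]$rate_hz
  nwin <- round(window_s * fs)
  acc <- numeric(nwin); count <- 0L
  dropped <- 0L
  for (i in seq_along(traces)) {
    x <- traces[[i]]$samples
    for (o in onset_list[[i]]) {
      i0 <- round(o * fs)
      if (i0 + nwin > length(x)) { dropped <- dropped + 1L; next }
      acc <- acc + x[i0 + seq_len(nwin)]
      count <- count + 1L
    }
  }
  if (dropped) warning(dropped, " window(s) ran past the trace end and ",
                       "were dropped")
  if (!count) stop("no usable windows")
  out <- waveform(acc / count, fs)
  attr(out, "n_windows") <- count
  out
}

#' Distortion-product otoacoustic emission analysis
#'
#' Coherently averages the epochs in the time domain and computes the
#' amplitude spectrum of the average at the epoch's native resolution
#' (dB re 20 uPa). The DP amplitude is read at the bin nearest
#' `2*f1 - f2` (with [ear_canal_spec()]'s bin-centered stimulation this
#' bin holds the DP exactly, with no leakage from the much stronger
#' primaries). The noise floor is the arithmetic mean of the amplitudes
#' at the 10 nearest bins on either side of the DP, excluding the DP
#' bin and one neighbor each side (about a 240 Hz neighborhood at the
#' native 23.4 Hz resolution).
#'
#' @param epochs Numeric matrix (epochs x samples).
#' @param spec The [ear_canal_spec()] describing the stimulation.
#' @param detect_margin_db DP is "detected" when it exceeds the noise
#'   floor by this margin.
#' @param n_noise_per_side Noise-floor bins per side.
#' @return An object of class `"dp_result"`: `dp_freq_hz`,
#'   `dp_amplitude_db`, `noise_floor_db`, `detected`, `freq_hz`,
#'   `amplitude_db`.
#' @export
dp_analysis <- function(epochs, spec, detect_margin_db = 6,
                        n_noise_per_side = 10L) {
  stopifnot(inherits(spec, "ear_canal_spec"), is.matrix(epochs))
  dp_freq <- 2 * spec$f1_hz - spec$f2_hz
  if (dp_freq <= 0) stop("DP frequency 2*f1 - f2 must be positive")
  avg <- colMeans(epochs)
  n <- length(avg)
  X <- stats::fft(avg)
  nb <- n %/% 2L + 1L
  amp <- 2 * Mod(X[seq_len(nb)]) / n
  freq <- (seq_len(nb) - 1) * spec$rate_hz / n
  amp_db <- 20 * log10(pmax(amp, 1e-30) / 20e-6)
  dp_bin <- which.min(abs(freq - dp_freq))
  lo <- dp_bin - 1L - seq_len(n_noise_per_side)
  hi <- dp_bin + 1L + seq_len(n_noise_per_side)
  noise_bins <- c(lo[lo >= 1L], hi[hi <= nb])
  floor_db <- 20 * log10(mean(amp[noise_bins]) / 20e-6)
  structure(list(dp_freq_hz = dp_freq,
                 dp_amplitude_db = amp_db[dp_bin],
                 noise_floor_db = floor_db,
                 detected = amp_db[dp_bin] >= floor_db + detect_margin_db,
                 freq_hz = freq, amplitude_db = amp_db),
            class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf(paste0("<dp_result: DP %.0f Hz at %.1f dB SPL, floor ",
                     "%.1f dB SPL, %sdetected>\n"),
              x$dp_freq_hz, x$dp_amplitude_db, x$noise_floor_db,
              if (x$detected) "" else "not "))
  invisible(x)
}

#' DPgram over a grid of f2 frequencies
#'
#' Generates ear-canal epochs for each f2 (keeping `f2/f1 = 1.25`) and
#' analyses them, assembling DP amplitude and noise floor versus f2.
#'
#' @param f2_grid_hz f2 frequencies, Hz.
#' @param base_spec An [ear_canal_spec()] used as template (its seed is
#'   offset per grid point).
#' @return A data frame: `f2_hz`, `dp_freq_hz`, `dp_amplitude_db`,
#'   `noise_floor_db`, `detected`.
#' @export
dp_gram <- function(f2_grid_hz, base_spec = ear_canal_spec()) {
  rows <- lapply(seq_along(f2_grid_hz), function(i) {
    sp <- ear_canal_spec(f2_hz = f2_grid_hz[i], l1_db = base_spec$l1_db,
                         l2_db = base_spec$l2_db,
                         dp_level_db = base_spec$dp_level_db,
                         cochlear_cutoff_hz = base_spec$cochlear_cutoff_hz,
                         epoch_len = base_spec$epoch_len,
                         n_epochs = base_spec$n_epochs,
                         rate_hz = base_spec$rate_hz,
                         noise_db = base_spec$noise_db,
                         seed = base_spec$seed + i)
    res <- dp_analysis(make_ear_canal_epochs(sp), sp)
    data.frame(f2_hz = sp$f2_hz, dp_freq_hz = res$dp_freq_hz,
               dp_amplitude_db = res$dp_amplitude_db,
               noise_floor_db = res$noise_floor_db,
               detected = res$detected)
  })
  do.call(rbind, rows)
}
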