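## Synthetic generators for every input the analysis pipeline consumes:
## syllables, bouted sequences, vocalization corpora, ECG / iEEG trials and
## ear-canal (DPOAE) epochs, each with planted, machine-readable ground truth.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic syllable
#'
#' Describes a harmonically structured, downward frequency-modulated
#' syllable with optional sinusoidal amplitude modulation (AM). Three
#' frequency-contour variants are supported: a plain downward sweep
#' (`"FM"`), a quasi-constant-frequency portion followed by a sweep
#' (`"qCF-FM"`), and a sinusoidally frequency-modulated contour (`"SFM"`).
#'
#' @param duration_s Syllable duration in seconds.
#' @param fundamental_start_hz,fundamental_end_hz Start and end of the
#'   fundamental's downward sweep, Hz.
#' @param n_harmonics Number of harmonics (amplitudes halve per harmonic).
#' @param am_rate_hz Sinusoidal AM rate in Hz; 0 means unmodulated.
#' @param am_depth AM depth in [0, 1].
#' @param fm_variant One of `"FM"`, `"qCF-FM"`, `"SFM"`.
#' @param ramp_s Linear onset/offset ramp, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @param peak_amplitude Peak amplitude of the rendered syllable relative
#'   to digital full scale.
#' @param qcf_fraction Fraction of the duration spent at the plateau for
#'   the qCF-FM variant.
#' @param sfm_rate_hz,sfm_depth_hz Rate and depth of the frequency
#'   modulation for the SFM variant.
#' @return A `"syllable_spec"` list.
#' @export
syllable_spec <- function(duration_s = 0.005,
                          fundamental_start_hz = 28000,
                          fundamental_end_hz = 18000,
                          n_harmonics = 3L,
                          am_rate_hz = 0,
                          am_depth = 0.9,
                          fm_variant = c("FM", "qCF-FM", "SFM"),
                          ramp_s = 0.0003,
                          rate_hz = 300000,
                          peak_amplitude = 0.5,
                          qcf_fraction = 0.4,
                          sfm_rate_hz = 400,
                          sfm_depth_hz = 3000) {
  fm_variant <- match.arg(fm_variant)
  stopifnot(duration_s > 0, am_depth >= 0, am_depth <= 1,
            n_harmonics >= 1, rate_hz > 0, ramp_s >= 0)
  env_dt <- 1e-4
  if (am_rate_hz >= 1 / (2 * env_dt) * 2)  # must sit below envelope Nyquist
    stop("am_rate_hz too high to be represented by the envelope grid")
  structure(list(duration_s = duration_s,
                 fundamental_start_hz = fundamental_start_hz,
                 fundamental_end_hz = fundamental_end_hz,
                 n_harmonics = as.integer(n_harmonics),
                 am_rate_hz = am_rate_hz, am_depth = am_depth,
                 fm_variant = fm_variant, ramp_s = ramp_s,
                 rate_hz = rate_hz, peak_amplitude = peak_amplitude,
                 qcf_fraction = qcf_fraction, sfm_rate_hz = sfm_rate_hz,
                 sfm_depth_hz = sfm_depth_hz),
            class = "syllable_spec")
}

# Instantaneous fundamental frequency trajectory for a syllable spec.
fundamental_trajectory <- function(spec, t) {
  dur <- spec$duration_s
  switch(spec$fm_variant,
    "FM" = spec$fundamental_start_hz +
      (spec$fundamental_end_hz - spec$fundamental_start_hz) * t / dur,
    "qCF-FM" = {
      t0 <- spec$qcf_fraction * dur
      f <- ifelse(t < t0, spec$fundamental_start_hz,
                  spec$fundamental_start_hz +
                    (spec$fundamental_end_hz - spec$fundamental_start_hz) *
                    (t - t0) / (dur - t0))
      f
    },
    "SFM" = {
      centre <- (spec$fundamental_start_hz + spec$fundamental_end_hz) / 2
      centre + spec$sfm_depth_hz * sin(2 * pi * spec$sfm_rate_hz * t)
    })
}

linear_ramp <- function(n, n_ramp) {
  w <- rep(1, n)
  if (n_ramp > 0 && n >= 2 * n_ramp) {
    r <- seq(0, 1, length.out = n_ramp)
    w[seq_len(n_ramp)] <- r
    w[(n - n_ramp + 1):n] <- rev(r)
  }
  w
}

#' Render a synthetic syllable
#'
#' Synthesizes the syllable described by `spec`: a sum of harmonics riding
#' the fundamental's frequency contour, multiplied by a sinusoidal AM
#' modulator `(1 + am_depth * sin(2*pi*am_rate_hz*t + phase)) /
#' (1 + am_depth)` (normalized so the peak amplitude is depth-invariant)
#' and linear edge ramps. The AM phase is drawn uniformly under `seed` and
#' recorded in the ground truth.
#'
#' @param spec A [syllable_spec()].
#' @param seed Integer seed (controls the AM phase draw).
#' @return A [waveform()] with attached `ground_truth` attribute
#'   (am_rate_hz, am_depth, am_phase, fm_variant).
#' @export
make_syllable <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "syllable_spec"))
  fs <- spec$rate_hz
  n <- max(2L, round(spec$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  f0 <- fundamental_trajectory(spec, t)
  if (max(f0) * spec$n_harmonics >= fs / 2)
    stop(sprintf(paste0("harmonic %d of the fundamental (max %.0f Hz) ",
                        "exceeds the Nyquist frequency %.0f Hz"),
                 spec$n_harmonics, max(f0), fs / 2))
  phase0 <- 2 * pi * cumsum(f0) / fs
  carrier <- numeric(n)
  for (h in seq_len(spec$n_harmonics))
    carrier <- carrier + 2^(-(h - 1)) * sin(h * phase0)
  am_phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  if (spec$am_rate_hz > 0) {
    mod <- (1 + spec$am_depth *
              sin(2 * pi * spec$am_rate_hz * t + am_phase)) /
      (1 + spec$am_depth)
  } else {
    mod <- rep(1, n)
  }
  x <- carrier * mod * linear_ramp(n, round(spec$ramp_s * fs))
  x <- x / max(abs(x)) * spec$peak_amplitude
  out <- waveform(x, fs)
  attr(out, "ground_truth") <- list(
    am_rate_hz = spec$am_rate_hz, am_depth = spec$am_depth,
    am_phase = if (spec$am_rate_hz > 0) am_phase else NA_real_,
    fm_variant = spec$fm_variant, duration_s = n / fs)
  out
}

#' Sinusoidally amplitude-modulated pure tone
#'
#' Full-depth AM tone: `sin(2*pi*carrier_hz*t) *
#' (1 + sin(2*pi*am_rate_hz*t - pi/2)) / 2`. With `am_rate_hz = 0` a plain
#' pure tone is returned.
#'
#' @param carrier_hz Carrier frequency, Hz (< `rate_hz / 2`).
#' @param am_rate_hz Modulation rate, Hz (0 = unmodulated).
#' @param duration_s Duration, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @param peak_amplitude Peak amplitude relative to full scale.
#' @return A [waveform()].
#' @export
make_am_tone <- function(carrier_hz, am_rate_hz, duration_s,
                         rate_hz = 192000, peak_amplitude = 0.9) {
  if (carrier_hz >= rate_hz / 2)
    stop("carrier_hz must be below the Nyquist frequency")
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  x <- sin(2 * pi * carrier_hz * t)
  if (am_rate_hz > 0)
    x <- x * (1 + sin(2 * pi * am_rate_hz * t - pi / 2)) / 2
  waveform(x / max(abs(x)) * peak_amplitude, rate_hz)
}

#' Layout of a bouted stimulus sequence
#'
#' @param n_bouts Number of bouts.
#' @param syllables_per_bout Syllable repetitions per bout.
#' @param isi_s Within-bout silent gap (offset to onset), seconds.
#' @param ibi_s Between-bout silent gap, seconds.
#' @param fade_s Linear fade applied to each syllable edge, seconds.
#' @return A `"sequence_layout"` list.
#' @export
sequence_layout <- function(n_bouts = 11L, syllables_per_bout = 6L,
                            isi_s = 0.014, ibi_s = 0.080, fade_s = 0.0002) {
  stopifnot(n_bouts >= 1, syllables_per_bout >= 1,
            isi_s >= 0, ibi_s >= 0, fade_s >= 0)
  structure(list(n_bouts = as.integer(n_bouts),
                 syllables_per_bout = as.integer(syllables_per_bout),
                 isi_s = isi_s, ibi_s = ibi_s, fade_s = fade_s),
            class = "sequence_layout")
}

#' Build a bouted stimulus sequence from one syllable
#'
#' Repeats the syllable `n_bouts * syllables_per_bout` times. Gaps are
#' silent intervals (offset-to-onset): consecutive syllables within a bout
#' are separated by `isi_s` of silence and consecutive bouts by `ibi_s`.
#' Each syllable copy is edge-faded over `fade_s`. The output RMS over the
#' syllable support is matched to the input syllable's RMS.
#'
#' @param syllable A [waveform()].
#' @param layout A [sequence_layout()].
#' @return A [waveform()] with attributes `onsets_s` (one onset per
#'   syllable copy) and `syllable_duration_s`.
#' @export
make_stimulus_sequence <- function(syllable, layout = sequence_layout()) {
  stopifnot(inherits(syllable, "waveform"), inherits(layout, "sequence_layout"))
  fs <- syllable$rate_hz
  syl <- syllable$samples
  n_syl <- length(syl)
  n_fade <- round(layout$fade_s * fs)
  if (n_fade * 2 > n_syl) stop("fade longer than half the syllable")
  syl_faded <- syl * linear_ramp(n_syl, n_fade)
  n_isi <- round(layout$isi_s * fs)
  n_ibi <- round(layout$ibi_s * fs)
  per_bout <- layout$syllables_per_bout
  total <- layout$n_bouts * (per_bout * n_syl + (per_bout - 1) * n_isi) +
    (layout$n_bouts - 1) * n_ibi
  out <- numeric(total)
  onsets <- integer(layout$n_bouts * per_bout)
  pos <- 0L
  k <- 0L
  for (b in seq_len(layout$n_bouts)) {
    for (s in seq_len(per_bout)) {
      k <- k + 1L
      onsets[k] <- pos
      out[pos + seq_len(n_syl)] <- syl_faded
      pos <- pos + n_syl
      if (s < per_bout) pos <- pos + n_isi
    }
    if (b < layout$n_bouts) pos <- pos + n_ibi
  }
  # match RMS over syllable support to the input syllable's RMS
  support <- unlist(lapply(onsets, function(o) o + seq_len(n_syl)))
  scale <- rms(syl) / rms(out[support])
  out <- out * scale
  res <- waveform(out, fs)
  attr(res, "onsets_s") <- onsets / fs
  attr(res, "syllable_duration_s") <- n_syl / fs
  res
}

#' Specification of a synthetic vocalization corpus
#'
#' @param n_sequences Number of sequences.
#' @param syllables_per_sequence Two numbers: the median and log-sd of a
#'   log-normal draw for syllable counts per sequence.
#' @param fam_fraction Target proportion of fast-AM syllables.
#' @param position_bias Non-negative; 0 places fast-AM syllables
#'   uniformly, larger values shift them toward the sequence start.
#' @param am_rate_distribution Two numbers: center and spread (Hz) of the
#'   normal draw for fast-AM rates (clipped to 1200-2400 Hz).
#' @param rate_hz Audio sampling rate, Hz.
#' @param seed Integer seed.
#' @return A `"corpus_spec"` list.
#' @export
corpus_spec <- function(n_sequences = 40L,
                        syllables_per_sequence = c(60, 0.3),
                        fam_fraction = 0.477,
                        position_bias = 0,
                        am_rate_distribution = c(1750, 200),
                        rate_hz = 300000,
                        seed = 1L) {
  stopifnot(fam_fraction >= 0, fam_fraction <= 1, position_bias >= 0,
            n_sequences >= 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 syllables_per_sequence = syllables_per_sequence,
                 fam_fraction = fam_fraction, position_bias = position_bias,
                 am_rate_distribution = am_rate_distribution,
                 rate_hz = rate_hz, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a synthetic distress-like vocalization corpus
#'
#' Draws bouted sequences of fast-AM (planted sinusoidal AM near the
#' corpus center rate) and slow-AM (weak, slow modulation) syllables.
#' Labels are drawn per syllable with probability `fam_fraction`; with
#' `position_bias > 0` fast-AM syllables are placed preferentially toward
#' the start of each sequence.
#'
#' @param spec A [corpus_spec()].
#' @param render One of `"sequences"`, `"syllables"`, `"none"`: whether to
#'   render full sequence audio, only individual syllable waveforms, or
#'   ground truth alone.
#' @return A list with `ground_truth` (one row per syllable: sequence,
#'   index, label, am_rate_hz, am_depth, norm_position, and when sequences
#'   are rendered, start_s/end_s), plus `sequences` and/or `syllables`
#'   lists of [waveform()]s depending on `render`.
#' @export
make_distress_corpus <- function(spec,
                                 render = c("sequences", "syllables", "none")) {
  stopifnot(inherits(spec, "corpus_spec"))
  render <- match.arg(render)
  if (spec$n_sequences == 0L) {
    warning("empty corpus requested (n_sequences = 0)")
    return(list(ground_truth = data.frame(), sequences = list(),
                syllables = list()))
  }
  with_seed(spec$seed, {
    gt_rows <- vector("list", spec$n_sequences)
    sequences <- if (render == "sequences") vector("list", spec$n_sequences)
    syllables <- if (render == "syllables") list()
    med <- spec$syllables_per_sequence[1]
    sdl <- spec$syllables_per_sequence[2]
    for (sq in seq_len(spec$n_sequences)) {
      n_syl <- max(1L, round(stats::rlnorm(1, log(med), sdl)))
      n_fast <- stats::rbinom(1, n_syl, spec$fam_fraction)
      labels <- rep("sAMV", n_syl)
      if (n_fast > 0) {
        p_norm <- if (n_syl > 1) (seq_len(n_syl) - 1) / (n_syl - 1) else 0.5
        w <- exp(-spec$position_bias * p_norm)
        labels[sample.int(n_syl, n_fast, prob = w)] <- "fAMV"
      }
      am_rate <- ifelse(labels == "fAMV",
                        pmin(2400, pmax(1200,
                          stats::rnorm(n_syl, spec$am_rate_distribution[1],
                                       spec$am_rate_distribution[2]))),
                        stats::runif(n_syl, 50, 300))
      am_depth <- ifelse(labels == "fAMV",
                         stats::runif(n_syl, 0.7, 1.0),
                         stats::runif(n_syl, 0.2, 0.5))
      dur <- stats::runif(n_syl, 0.004, 0.008)
      f_hi <- stats::runif(n_syl, 25000, 30000)
      f_lo <- stats::runif(n_syl, 15000, 20000)
      seeds <- sample.int(.Machine$integer.max, n_syl)
      gt <- data.frame(
        sequence = sq, index = seq_len(n_syl), label = labels,
        am_rate_hz = am_rate, am_depth = am_depth, duration_s = dur,
        norm_position = if (n_syl > 1)
          (seq_len(n_syl) - 1) / (n_syl - 1) else 0.5,
        stringsAsFactors = FALSE)
      if (render != "none") {
        syl_waves <- lapply(seq_len(n_syl), function(i) {
          sp <- syllable_spec(duration_s = dur[i],
                              fundamental_start_hz = f_hi[i],
                              fundamental_end_hz = f_lo[i],
                              am_rate_hz = am_rate[i],
                              am_depth = am_depth[i],
                              rate_hz = spec$rate_hz)
          make_syllable(sp, seed = seeds[i])
        })
        if (render == "syllables") {
          syllables <- c(syllables, syl_waves)
        } else {
          # bouted assembly: bouts of ~6, 14 ms ISI, 80 ms IBI
          fs <- spec$rate_hz
          n_isi <- round(0.014 * fs); n_ibi <- round(0.080 * fs)
          pieces <- list(); starts <- numeric(n_syl); pos <- 0L
          for (i in seq_len(n_syl)) {
            starts[i] <- pos
            pieces[[length(pieces) + 1L]] <- syl_waves[[i]]$samples
            pos <- pos + length(syl_waves[[i]]$samples)
            if (i < n_syl) {
              gap <- if (i %% 6 == 0) n_ibi else n_isi
              pieces[[length(pieces) + 1L]] <- numeric(gap)
              pos <- pos + gap
            }
          }
          sequences[[sq]] <- waveform(unlist(pieces), fs)
          gt$start_s <- starts / fs
          gt$end_s <- gt$start_s + vapply(syl_waves, function(w)
            length(w$samples), numeric(1)) / fs
        }
      }
      gt_rows[[sq]] <- gt
    }
    out <- list(ground_truth = do.call(rbind, gt_rows))
    if (render == "sequences") out$sequences <- sequences
    if (render == "syllables") out$syllables <- syllables
    out
  })
}

#' Specification of a synthetic ECG trial
#'
#' @param rate_hz Sampling rate, Hz.
#' @param pre_s,post_s Seconds of recording before/after stimulus onset.
#' @param baseline_bpm Baseline heart rate, beats per minute.
#' @param response_gain_bpm Peak heart-rate increase after stimulus onset.
#' @param response_rise_s,response_decay_s Time constants of the causal
#'   rise/decay response kernel, seconds.
#' @param qrs_polarity Sign of the dominant QRS deflection (-1 or 1).
#' @param noise_sd White-noise SD relative to QRS amplitude.
#' @param artifact_rate Expected number of movement-artifact bursts per
#'   trial (Poisson).
#' @param seed Integer seed.
#' @return An `"ecg_trial_spec"` list.
#' @export
ecg_trial_spec <- function(rate_hz = 9600, pre_s = 5, post_s = 10,
                           baseline_bpm = 480, response_gain_bpm = 0,
                           response_rise_s = 0.5, response_decay_s = 2,
                           qrs_polarity = -1, noise_sd = 0.05,
                           artifact_rate = 0, seed = 1L) {
  stopifnot(baseline_bpm > 0, rate_hz > 0, pre_s >= 0, post_s > 0)
  structure(list(rate_hz = rate_hz, pre_s = pre_s, post_s = post_s,
                 baseline_bpm = baseline_bpm,
                 response_gain_bpm = response_gain_bpm,
                 response_rise_s = response_rise_s,
                 response_decay_s = response_decay_s,
                 qrs_polarity = sign(qrs_polarity), noise_sd = noise_sd,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "ecg_trial_spec")
}

# Causal rise/decay response kernel, peak-normalized to 1.
hr_response_kernel <- function(t, rise_s, decay_s) {
  g <- ifelse(t > 0, exp(-t / decay_s) - exp(-t / rise_s), 0)
  tp <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  g / (exp(-tp / decay_s) - exp(-tp / rise_s))
}

# Biphasic QRS template with the dominant deflection at its center sample.
qrs_template <- function(fs, polarity = -1, width_s = 0.012) {
  n <- round(width_s * fs)
  if (n %% 2 == 0) n <- n + 1L
  t <- seq(-1, 1, length.out = n)
  main <- exp(-(t / 0.25)^2)
  side <- 0.35 * exp(-((t - 0.55) / 0.2)^2) + 0.25 * exp(-((t + 0.55) / 0.2)^2)
  polarity * (main - side)
}

#' Generate a synthetic ECG trial with planted beat times
#'
#' Beat times realize the instantaneous rate `r(t) = baseline_bpm +
#' response_gain_bpm * g(t - onset)` where `g` is a causal rise/decay
#' kernel (peak 1). Each beat is stamped with a biphasic QRS template
#' whose dominant deflection carries `qrs_polarity`; white noise and
#' optional movement-artifact spike bursts (inter-spike intervals below
#' 62 ms) are added on top.
#'
#' @param spec An [ecg_trial_spec()].
#' @param stimulus_onset_s Stimulus onset time, seconds from trace start;
#'   defaults to `pre_s`.
#' @return A [waveform()] with `ground_truth` attribute: exact
#'   `beat_times_s`, `artifact_times_s`, and the planted rate function
#'   parameters.
#' @export
make_ecg_trial <- function(spec, stimulus_onset_s = spec$pre_s) {
  stopifnot(inherits(spec, "ecg_trial_spec"))
  fs <- spec$rate_hz
  dur <- spec$pre_s + spec$post_s
  with_seed(spec$seed, {
    dt <- 1e-3
    tt <- seq(0, dur, by = dt)
    r <- spec$baseline_bpm + spec$response_gain_bpm *
      hr_response_kernel(tt - stimulus_onset_s,
                         spec$response_rise_s, spec$response_decay_s)
    if (any(r <= 0)) stop("instantaneous rate must stay positive")
    beats_cum <- cumsum(r / 60) * dt
    n_beats <- floor(max(beats_cum))
    beat_times <- stats::approx(beats_cum, tt, xout = seq_len(n_beats))$y
    beat_times <- beat_times[!is.na(beat_times)]
    n <- round(dur * fs)
    x <- stats::rnorm(n, 0, spec$noise_sd)
    tmpl <- qrs_template(fs, spec$qrs_polarity)
    half <- (length(tmpl) - 1L) %/% 2L
    for (bt in beat_times) {
      c0 <- round(bt * fs) + 1L
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
    }
    art_times <- numeric(0)
    n_art <- stats::rpois(1, spec$artifact_rate)
    if (n_art > 0) {
      for (a in seq_len(n_art)) {
        t0 <- stats::runif(1, 0.2, dur - 0.2)
        gap <- stats::runif(1, 0.015, 0.055)  # below the 62 ms artifact rule
        for (ts in c(t0, t0 + gap)) {
          c0 <- round(ts * fs) + 1L
          idx <- (c0 - half):(c0 + half)
          ok <- idx >= 1L & idx <= n
          x[idx[ok]] <- x[idx[ok]] + 1.6 * tmpl[ok]
        }
        art_times <- c(art_times, t0, t0 + gap)
      }
    }
    out <- waveform(x, fs)
    attr(out, "ground_truth") <- list(
      beat_times_s = beat_times, artifact_times_s = art_times,
      stimulus_onset_s = stimulus_onset_s,
      baseline_bpm = spec$baseline_bpm,
      response_gain_bpm = spec$response_gain_bpm,
      response_rise_s = spec$response_rise_s,
      response_decay_s = spec$response_decay_s)
    out
  })
}

#' Specification of a synthetic iEEG trial
#'
#' @param rate_hz Sampling rate, Hz.
#' @param ffr_gain Amplitude of the stimulus-locked sinusoid at the
#'   stimulus AM rate during each syllable (0 for demodulated stimuli).
#' @param evoked_gain Amplitude of the per-syllable evoked transient.
#' @param noise_exponent Exponent alpha of the 1/f^alpha background.
#' @param noise_sd Standard deviation of the background noise.
#' @param silent_baseline_s Stimulus-free baseline before the first onset
#'   (>= 1.5 s).
#' @param tail_s Silence appended after the stimulus, seconds.
#' @param seed Integer seed.
#' @return An `"ieeg_trial_spec"` list.
#' @export
ieeg_trial_spec <- function(rate_hz = 9600, ffr_gain = 1, evoked_gain = 1,
                            noise_exponent = 1, noise_sd = 1,
                            silent_baseline_s = 1.7, tail_s = 0.5,
                            seed = 1L) {
  if (silent_baseline_s < 1.5)
    stop("silent_baseline_s must be at least 1.5 s")
  structure(list(rate_hz = rate_hz, ffr_gain = ffr_gain,
                 evoked_gain = evoked_gain,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 silent_baseline_s = silent_baseline_s, tail_s = tail_s,
                 seed = as.integer(seed)),
            class = "ieeg_trial_spec")
}

# 1/f^alpha Gaussian noise via spectral shaping, unit SD.
one_over_f_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))             # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)               # mirror for negative frequencies
  W <- W / f^(alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic iEEG trial with a planted frequency-following
#' response
#'
#' Background 1/f^alpha noise over the whole trace; during each syllable
#' window a damped evoked transient plus `ffr_gain *
#' sin(2*pi*stimulus_am_rate_hz*t)` (t relative to syllable onset) is
#' added. At least 1.5 s of stimulus-free baseline precedes the first
#' onset.
#'
#' @param spec An [ieeg_trial_spec()].
#' @param onsets_s Stimulus syllable onsets, seconds relative to stimulus
#'   start.
#' @param syllable_duration_s Duration of each syllable, seconds.
#' @param stimulus_am_rate_hz AM rate of the stimulus, Hz
#'   (< `rate_hz / 2`).
#' @return A [waveform()] with attributes `onsets_s` (absolute, within the
#'   trace) and `ground_truth`.
#' @export
make_ieeg_trial <- function(spec, onsets_s, syllable_duration_s,
                            stimulus_am_rate_hz) {
  stopifnot(inherits(spec, "ieeg_trial_spec"))
  if (stimulus_am_rate_hz >= spec$rate_hz / 2)
    stop("stimulus_am_rate_hz must be below the Nyquist frequency")
  fs <- spec$rate_hz
  stim_len <- max(onsets_s) + syllable_duration_s
  dur <- spec$silent_baseline_s + stim_len + spec$tail_s
  n <- round(dur * fs)
  with_seed(spec$seed, {
    x <- spec$noise_sd * one_over_f_noise(n, spec$noise_exponent)
    abs_onsets <- spec$silent_baseline_s + onsets_s
    n_win <- round(syllable_duration_s * fs)
    tw <- (seq_len(n_win) - 1) / fs
    evoked <- spec$evoked_gain * exp(-tw / 0.004) * sin(2 * pi * 600 * tw)
    for (o in abs_onsets) {
      i0 <- round(o * fs)
      idx <- i0 + seq_len(n_win)
      idx <- idx[idx <= n]
      add <- evoked[seq_along(idx)]
      if (spec$ffr_gain > 0)
        add <- add + spec$ffr_gain *
          sin(2 * pi * stimulus_am_rate_hz * tw[seq_along(idx)])
      x[idx] <- x[idx] + add
    }
    out <- waveform(x, fs)
    attr(out, "onsets_s") <- abs_onsets
    attr(out, "ground_truth") <- list(
      ffr_gain = spec$ffr_gain, evoked_gain = spec$evoked_gain,
      stimulus_am_rate_hz = stimulus_am_rate_hz,
      silent_baseline_s = spec$silent_baseline_s,
      syllable_duration_s = syllable_duration_s)
    out
  })
}

#' Specification of synthetic ear-canal (DPOAE) epochs
#'
#' Two-tone stimulation with `f2 / f1 = 1.25`; a cubic distortion product
#' at `2*f1 - f2` is planted at `dp_level_db` whenever `f2_hz` is at or
#' above `cochlear_cutoff_hz` (emulating a cochlea insensitive below the
#' cutoff).
#'
#' @param f2_hz Frequency of the f2 primary, Hz; `f1_hz = f2_hz / 1.25`.
#' @param l1_db,l2_db Primary levels, dB SPL.
#' @param dp_level_db Planted DP level, dB SPL.
#' @param cochlear_cutoff_hz f2 frequencies below this plant no DP.
#' @param epoch_len Samples per epoch.
#' @param n_epochs Number of epochs.
#' @param rate_hz Sampling rate, Hz.
#' @param noise_db Level controlling the per-epoch white-noise floor, dB
#'   SPL (time-domain SD in the same pressure units as the tones).
#' @param seed Integer seed.
#' @return An `"ear_canal_spec"` list.
#' @export
ear_canal_spec <- function(f2_hz = 18000, l1_db = 60, l2_db = 50,
                           dp_level_db = 20, cochlear_cutoff_hz = 5000,
                           epoch_len = 8192L, n_epochs = 100L,
                           rate_hz = 192000, noise_db = 30, seed = 1L) {
  # snap f2 to a multiple of 5*(rate/epoch_len): f1 = f2/1.25 and the DP
  # 2*f1 - f2 then fall exactly on FFT bins of one epoch (the standard
  # trick in DPOAE rigs to avoid spectral leakage of the primaries),
  # while keeping f2/f1 = 1.25 exact.
  quantum <- 5 * rate_hz / epoch_len
  f2_hz <- max(1, round(f2_hz / quantum)) * quantum
  f1_hz <- f2_hz / 1.25
  if (2 * f1_hz - f2_hz <= 0) stop("2*f1 - f2 must be positive")
  structure(list(f2_hz = f2_hz, f1_hz = f1_hz, l1_db = l1_db, l2_db = l2_db,
                 dp_level_db = dp_level_db,
                 cochlear_cutoff_hz = cochlear_cutoff_hz,
                 epoch_len = as.integer(epoch_len),
                 n_epochs = as.integer(n_epochs), rate_hz = rate_hz,
                 noise_db = noise_db, seed = as.integer(seed)),
            class = "ear_canal_spec")
}

# Amplitude (pressure units, reference 20 uPa) of a level in dB SPL.
db_spl_to_amp <- function(db) 10^(db / 20) * 20e-6

#' Generate synthetic ear-canal epochs with a planted distortion product
#'
#' Each epoch contains the two primaries (phase-locked across epochs),
#' the planted cubic DP at `2*f1 - f2` when `f2_hz >=
#' cochlear_cutoff_hz`, and independent white noise.
#'
#' @param spec An [ear_canal_spec()].
#' @return A numeric matrix (`n_epochs` x `epoch_len`) with a
#'   `ground_truth` attribute.
#' @export
make_ear_canal_epochs <- function(spec) {
  stopifnot(inherits(spec, "ear_canal_spec"))
  with_seed(spec$seed, {
    t <- (seq_len(spec$epoch_len) - 1) / spec$rate_hz
    phases <- stats::runif(3, 0, 2 * pi)
    base <- db_spl_to_amp(spec$l1_db) * sin(2 * pi * spec$f1_hz * t + phases[1]) +
      db_spl_to_amp(spec$l2_db) * sin(2 * pi * spec$f2_hz * t + phases[2])
    dp_planted <- spec$f2_hz >= spec$cochlear_cutoff_hz
    dp_freq <- 2 * spec$f1_hz - spec$f2_hz
    if (dp_planted)
      base <- base + db_spl_to_amp(spec$dp_level_db) *
        sin(2 * pi * dp_freq * t + phases[3])
    noise_sd <- db_spl_to_amp(spec$noise_db)
    m <- matrix(stats::rnorm(spec$n_epochs * spec$epoch_len, 0, noise_sd),
                nrow = spec$n_epochs, byrow = TRUE)
    m <- sweep(m, 2, base, "+")
    attr(m, "ground_truth") <- list(
      dp_planted = dp_planted, dp_freq_hz = dp_freq,
      dp_level_db = if (dp_planted) spec$dp_level_db else NA_real_,
      noise_db = spec$noise_db)
    m
  })
}
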