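## Desk-scale orchestration of the full study: synthetic corpora and
## trials in, tables and a reproduction report out.

# Deterministic sub-seed derivation (kept well below 2^31).
derive_seed <- function(master, k) as.integer((master * 7919 + k) %% 2147483647)

#' Pipeline run configuration
#'
#' Bundles every stage's parameters with the study-design defaults: a
#' distress corpus with 47.7% fast-AM syllables and a social corpus with
#' 6.3%; six stimulus conditions (FM, qCF-FM, SFM syllables, natural
#' and demodulated) presented as 11 bouts x 6 syllables; 12 ECG animals
#' with 10 trials per condition; 11 iEEG animals.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param distress_sequences,social_sequences Corpus sizes.
#' @param syllables_per_sequence Median and log-sd of per-sequence
#'   syllable counts.
#' @param distress_fam_fraction,social_fam_fraction Planted fast-AM
#'   fractions.
#' @param position_bias Planted left-skew of fast-AM positions in the
#'   distress corpus.
#' @param n_train_per_class Training syllables per class for the SVM.
#' @param n_ecg_animals,n_ecg_trials,n_ieeg_animals Physiology design.
#' @param ecg_artifact_rate Expected movement artifacts per ECG trial.
#' @param hr_gain_modulated,hr_gain_demodulated Planted peak HR
#'   increases (bpm) for natural and demodulated stimuli.
#' @param ffr_gain_modulated,ffr_gain_demodulated Planted FFR amplitudes.
#' @param stimulus_rate_hz Sampling rate of the physiology stimuli, Hz.
#' @param corpus_rate_hz Sampling rate of the corpora, Hz.
#' @return A `"run_config"` list.
#' @export
run_config <- function(seed = 1L,
                       distress_sequences = 40L, social_sequences = 25L,
                       syllables_per_sequence = c(60, 0.3),
                       distress_fam_fraction = 0.477,
                       social_fam_fraction = 0.063,
                       position_bias = 0.6,
                       n_train_per_class = 50L,
                       n_ecg_animals = 12L, n_ecg_trials = 10L,
                       n_ieeg_animals = 11L,
                       ecg_artifact_rate = 0,
                       hr_gain_modulated = 80, hr_gain_demodulated = 35,
                       ffr_gain_modulated = 1.5, ffr_gain_demodulated = 0,
                       stimulus_rate_hz = 192000,
                       corpus_rate_hz = 300000) {
  structure(as.list(environment()), class = "run_config")
}

#' Synthetic training set for the fast-AM / slow-AM classifier
#'
#' Generates `n_per_class` fast-AM syllables (AM rates and depths drawn
#' uniformly from the given ranges; the default range spans the
#' frequencies-of-interest band, matching the rates the corpus
#' generator draws) and `n_per_class` unmodulated syllables, and
#' extracts TMS feature vectors.
#'
#' @param n_per_class Syllables per class.
#' @param seed Integer seed.
#' @param rate_hz Sampling rate.
#' @param am_rate_range Fast-AM rate range, Hz.
#' @param am_depth_range Fast-AM depth range.
#' @return A list: `features` matrix, `labels` ("fAMV"/"sAMV").
#' @export
make_training_set <- function(n_per_class = 50L, seed = 1L,
                              rate_hz = 300000,
                              am_rate_range = c(1200, 2400),
                              am_depth_range = c(0.7, 1.0)) {
  pars <- with_seed(seed, {
    list(rate = stats::runif(n_per_class, am_rate_range[1],
                             am_rate_range[2]),
         depth = stats::runif(n_per_class, am_depth_range[1],
                              am_depth_range[2]),
         dur = stats::runif(2 * n_per_class, 0.004, 0.008),
         seeds = sample.int(.Machine$integer.max, 2 * n_per_class))
  })
  feats <- lapply(seq_len(2 * n_per_class), function(i) {
    fast <- i <= n_per_class
    sp <- syllable_spec(duration_s = pars$dur[i],
                        am_rate_hz = if (fast) pars$rate[i] else 0,
                        am_depth = if (fast) pars$depth[i] else 0,
                        rate_hz = rate_hz)
    syl <- make_syllable(sp, seed = pars$seeds[i])
    tms_feature_vector(temporal_modulation_spectrum(amplitude_envelope(syl)))
  })
  list(features = do.call(rbind, feats),
       labels = rep(c("fAMV", "sAMV"), each = n_per_class))
}

# Segment the rendered sequences of a corpus and align segments to the
# generator's ground truth by temporal overlap.
segment_corpus <- function(corpus, rate_hz) {
  gt <- corpus$ground_truth
  out <- vector("list", length(corpus$sequences))
  for (sq in seq_along(corpus$sequences)) {
    segs <- segment_syllables(corpus$sequences[[sq]])
    g <- gt[gt$sequence == sq, ]
    match_idx <- rep(NA_integer_, nrow(g))
    for (i in seq_len(nrow(g))) {
      ov <- pmin(segs$end_s, g$end_s[i]) - pmax(segs$start_s, g$start_s[i])
      if (length(ov) && max(ov) > 0) match_idx[i] <- which.max(ov)
    }
    out[[sq]] <- list(segments = segs, match = match_idx)
  }
  out
}

#' Run the acoustic arm of the study on synthetic corpora
#'
#' Generates distress-like and social-like corpora, segments the
#' rendered sequences, extracts per-syllable features, trains the SVM on
#' a separate synthetic training set, classifies both corpora, runs the
#' sequence-position analysis, and contrasts classified groups on FOI
#' area, peak frequency, spectral area and HND (rank-sum p and Cliff's
#' delta). Ground-truth recovery metrics are included throughout.
#'
#' @param config A [run_config()].
#' @return A `"report_section"` list; see its elements.
#' @export
run_acoustics <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  train <- make_training_set(config$n_train_per_class,
                             seed = derive_seed(config$seed, 1),
                             rate_hz = config$corpus_rate_hz)
  model <- train_classifier(train$features, train$labels,
                            seed = derive_seed(config$seed, 2))
  analyse_corpus <- function(n_seq, fam, bias, seed_k) {
    corpus <- make_distress_corpus(corpus_spec(
      n_sequences = n_seq,
      syllables_per_sequence = config$syllables_per_sequence,
      fam_fraction = fam, position_bias = bias,
      rate_hz = config$corpus_rate_hz,
      seed = derive_seed(config$seed, seed_k)))
    seg <- segment_corpus(corpus, config$corpus_rate_hz)
    gt <- corpus$ground_truth
    feats <- vector("list", nrow(gt))
    fvecs <- vector("list", nrow(gt))
    row <- 0L
    for (sq in seq_along(corpus$sequences)) {
      g <- gt[gt$sequence == sq, ]
      for (i in seq_len(nrow(g))) {
        row <- row + 1L
        mi <- seg[[sq]]$match[i]
        if (is.na(mi)) next
        syl <- segment_waveform(corpus$sequences[[sq]],
                                seg[[sq]]$segments[mi, ])
        env <- amplitude_envelope(syl)
        tms <- temporal_modulation_spectrum(env)
        ps <- power_spectrum_200hz(syl)
        feats[[row]] <- data.frame(
          sequence = sq, index = g$index[i],
          foi_area = tms$foi_area, bmf_hz = tms$bmf_hz,
          peak_frequency_hz = ps$peak_frequency_hz,
          spectral_area_khz = ps$spectral_area_khz, hnd = ps$hnd)
        fvecs[[row]] <- tms_feature_vector(tms)
      }
    }
    found <- !vapply(fvecs, is.null, logical(1))
    features <- do.call(rbind, c(feats[found], list(make.row.names = FALSE)))
    cls <- classify_syllables(model, do.call(rbind, fvecs[found]))
    features$label <- cls$labels
    gt_found <- gt[found, ]
    labels_by_seq <- split(features$label, features$sequence)
    posan <- position_analysis(labels_by_seq,
                               seed = derive_seed(config$seed, seed_k + 10))
    contrast <- lapply(c(foi_area = "foi_area",
                         peak_frequency_hz = "peak_frequency_hz",
                         spectral_area_khz = "spectral_area_khz",
                         hnd = "hnd"), function(v) {
      effect_report(features[[v]][features$label == "fAMV"],
                    features[[v]][features$label == "sAMV"])
    })
    list(n_syllables = nrow(gt), n_segmented = sum(found),
         planted_fraction = mean(gt$label == "fAMV"),
         recovered_fraction = cls$fraction,
         label_agreement = mean(features$label == gt_found$label),
         position = posan[c("ks_stat", "ks_p", "halves_p", "defined")],
         observed_median_position =
           stats::median(posan$observed),
         contrast = contrast,
         features = features)
  }
  distress <- analyse_corpus(config$distress_sequences,
                             config$distress_fam_fraction,
                             config$position_bias, 3)
  social <- analyse_corpus(config$social_sequences,
                           config$social_fam_fraction, 0, 4)
  structure(list(stage = "acoustics", cv_error = model$cv_error,
                 distress = distress, social = social,
                 config = config),
            class = "report_section")
}

# Build the six physiology stimuli: three syllable variants, natural and
# demodulated, as bouted sequences. Gates on synthesis error <= 2%.
build_stimulus_set <- function(config, am_rate_hz = 1700) {
  variants <- c("FM", "qCF-FM", "SFM")
  stim <- list()
  for (v in variants) {
    syl <- make_syllable(syllable_spec(fm_variant = v,
                                       am_rate_hz = am_rate_hz,
                                       am_depth = 0.9,
                                       rate_hz = config$stimulus_rate_hz),
                         seed = derive_seed(config$seed, 20 + match(v, variants)))
    dem <- demodulate(syl)
    if (dem$report$synthesis_error_pct > 2)
      stop("synthesis error gate failed for variant ", v, ": ",
           round(dem$report$synthesis_error_pct, 3), "%")
    for (treat in c("natural", "demodulated")) {
      wavein <- if (treat == "natural") syl else dem$wave
      seqw <- make_stimulus_sequence(wavein, sequence_layout())
      stim[[paste(v, treat, sep = "_")]] <- list(
        variant = v, treatment = treat, sequence = seqw,
        onsets_s = attr(seqw, "onsets_s"),
        syllable_duration_s = attr(seqw, "syllable_duration_s"),
        am_rate_hz = if (treat == "natural") am_rate_hz else 0,
        synthesis_error_pct = dem$report$synthesis_error_pct)
    }
  }
  stim
}

#' Run the physiology arm of the study on synthetic trials
#'
#' Builds the six stimulus sequences (three syllable variants, natural
#' and MPS-demodulated, gated on synthesis error below 2%), simulates
#' ECG trials across animals and conditions with planted heart-rate
#' gains (larger for modulated stimuli), simulates iEEG traces with a
#' planted frequency-following response for modulated stimuli only, and
#' measures DPgrams over the coarse and fine f2 grids.
#'
#' @param config A [run_config()].
#' @param skip_dpgram If `TRUE` the DPgram stage is omitted.
#' @return A `"report_section"` list with `stimuli`, `hr` (trial table
#'   and per-variant paired statistics), `ffr` (per animal x condition
#'   band powers and per-variant paired statistics), `rejected_fraction`
#'   and `dpgram`.
#' @export
run_physiology <- function(config = run_config(), skip_dpgram = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stim <- build_stimulus_set(config)
  variants <- c("FM", "qCF-FM", "SFM")

  ## --- ECG arm ---
  trials <- list(); k <- 0L
  for (a in seq_len(config$n_ecg_animals)) {
    for (s in names(stim)) {
      gain <- if (stim[[s]]$treatment == "natural")
        config$hr_gain_modulated else config$hr_gain_demodulated
      for (tr in seq_len(config$n_ecg_trials)) {
        k <- k + 1L
        spec <- ecg_trial_spec(response_gain_bpm = gain,
                               artifact_rate = config$ecg_artifact_rate,
                               seed = derive_seed(config$seed,
                                                  1000 + k))
        trial <- make_ecg_trial(spec)
        qrs <- detect_qrs(trial)
        hc <- hr_curve(qrs, stimulus_onset_s = spec$pre_s)
        trials[[k]] <- data.frame(
          animal = a, variant = stim[[s]]$variant,
          treatment = stim[[s]]$treatment, trial = tr,
          area = hc$response_area, valid = hc$valid)
      }
    }
  }
  trial_tab <- do.call(rbind, trials)
  hr_stats <- lapply(stats::setNames(variants, variants), function(v) {
    tv <- trial_tab[trial_tab$variant == v, ]
    tv$condition <- tv$treatment
    hr_condition_summary(tv, test_pair = c("natural", "demodulated"))
  })

  ## --- iEEG arm ---
  ffr_rows <- list(); k <- 0L
  for (a in seq_len(config$n_ieeg_animals)) {
    for (s in names(stim)) {
      k <- k + 1L
      st <- stim[[s]]
      gain <- if (st$treatment == "natural")
        config$ffr_gain_modulated else config$ffr_gain_demodulated
      spec <- ieeg_trial_spec(ffr_gain = gain,
                              seed = derive_seed(config$seed, 5000 + k))
      trace <- make_ieeg_trial(spec, st$onsets_s, st$syllable_duration_s,
                               stimulus_am_rate_hz = 1700)
      sp <- multitaper_ffr(trace, attr(trace, "onsets_s"))
      ffr_rows[[k]] <- data.frame(
        animal = a, variant = st$variant, treatment = st$treatment,
        band_power = sp$ffr_band_power)
    }
  }
  ffr_tab <- do.call(rbind, ffr_rows)
  ffr_stats <- lapply(stats::setNames(variants, variants), function(v) {
    tv <- ffr_tab[ffr_tab$variant == v, ]
    nat <- tv$band_power[tv$treatment == "natural"]
    dem <- tv$band_power[tv$treatment == "demodulated"]
    list(p = paired_and_unpaired_tests(nat, dem, paired = TRUE)$p,
         all_larger = all(nat > dem))
  })

  ## --- DPOAE arm ---
  dpg <- NULL
  if (!skip_dpgram) {
    base <- ear_canal_spec(seed = derive_seed(config$seed, 9000))
    dpg <- list(coarse = dp_gram(seq(1000, 25000, by = 1000), base),
                fine = dp_gram(seq(1000, 3200, by = 200), base))
  }

  structure(list(
    stage = "physiology",
    stimuli = lapply(stim, function(s)
      s[c("variant", "treatment", "am_rate_hz", "synthesis_error_pct")]),
    hr = list(trials = trial_tab, stats = hr_stats),
    rejected_fraction = mean(!trial_tab$valid),
    ffr = list(table = ffr_tab, stats = ffr_stats),
    dpgram = dpg, config = config),
    class = "report_section")
}

#' @export
print.report_section <- function(x, ...) {
  cat(sprintf("<report_section: %s>\n", x$stage))
  if (x$stage == "acoustics") {
    cat(sprintf("  classifier CV error: %.1f%%\n", 100 * x$cv_error))
    for (nm in c("distress", "social"))
      cat(sprintf("  %s: %d syllables, planted %.3f, recovered %.3f, agreement %.3f\n",
                  nm, x[[nm]]$n_syllables, x[[nm]]$planted_fraction,
                  x[[nm]]$recovered_fraction, x[[nm]]$label_agreement))
  } else {
    cat(sprintf("  rejected ECG trials: %.1f%%\n",
                100 * x$rejected_fraction))
    for (v in names(x$hr$stats))
      cat(sprintf("  HR %s: paired p = %.4g\n", v, x$hr$stats[[v]]$p))
  }
  invisible(x)
}
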