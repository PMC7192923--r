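## Amplitude-threshold syllable segmentation and bout grouping.

#' Segment a recording into syllables by amplitude threshold
#'
#' A syllable is a maximal region where the smoothed signal envelope
#' (analytic-signal magnitude) stays at or above `threshold_frac` of
#' digital full scale
#' (|x| = 1). Sub-threshold runs shorter than `min_gap_s` are bridged
#' (the level must stay below threshold for at least `min_gap_s` to end a
#' syllable), and resulting segments shorter than `min_dur_s` are dropped
#' as clicks. The threshold is referenced to full scale, not to the
#' per-file maximum, so detection is deliberately sensitive to absolute
#' level.
#'
#' @param rec A [waveform()].
#' @param threshold_frac Detection threshold as a fraction of full scale.
#' @param min_gap_s Minimum sub-threshold run that separates syllables,
#'   seconds.
#' @param min_dur_s Minimum syllable duration, seconds.
#' @param smooth_s Envelope smoothing window for detection, seconds.
#' @return A data frame with one row per segment: `start_s`, `end_s`
#'   (half-open, seconds) and `start_idx`, `end_idx` (1-based sample
#'   indices, inclusive start / exclusive end).
#' @export
segment_syllables <- function(rec, threshold_frac = 0.041,
                              min_gap_s = 0.001, min_dur_s = 0.0005,
                              smooth_s = 1e-4) {
  stopifnot(inherits(rec, "waveform"))
  x <- rec$samples
  if (!length(x)) stop("empty recording")
  fs <- rec$rate_hz
  w <- max(1L, round(smooth_s * fs))
  env <- analytic_magnitude(x)           # envelope tracks the peak, not
  if (w > 1L) {                          # the rectified mean
    k <- rep(1 / w, w)
    env <- stats::filter(env, k, sides = 2)
    env[is.na(env)] <- 0
    env <- as.numeric(env)
  }
  above <- env >= threshold_frac
  if (!any(above)) return(empty_segments())
  r <- rle(above)
  # bridge sub-threshold runs shorter than min_gap_s (interior only)
  min_gap <- round(min_gap_s * fs)
  if (length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    bridge <- interior[!r$values[interior] & r$lengths[interior] < min_gap]
    r$values[bridge] <- TRUE
  }
  above <- inverse.rle(r)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  min_dur <- round(min_dur_s * fs)
  long_enough <- (ends - starts + 1L) >= min_dur
  starts <- starts[long_enough]; ends <- ends[long_enough]
  if (!length(starts)) return(empty_segments())
  data.frame(start_s = (starts - 1L) / fs, end_s = ends / fs,
             start_idx = starts, end_idx = ends + 1L)
}

empty_segments <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             start_idx = integer(0), end_idx = integer(0))
}

#' Extract the waveform of one segment
#'
#' @param rec A [waveform()].
#' @param segment One row of the data frame returned by
#'   [segment_syllables()].
#' @return A [waveform()] slice.
#' @export
segment_waveform <- function(rec, segment) {
  waveform(rec$samples[segment$start_idx:(segment$end_idx - 1L)],
           rec$rate_hz, rec$calibration_db_fs)
}

#' Group time-ordered segments into multi-syllabic bouts
#'
#' Consecutive segments whose offset-to-onset gap is at most `bout_gap_s`
#' share a bout.
#'
#' @param segments Data frame from [segment_syllables()] (time-ordered).
#' @param bout_gap_s Maximum within-bout gap, seconds.
#' @return The `segments` data frame with an added integer `bout` column.
#' @export
group_bouts <- function(segments, bout_gap_s = 0.030) {
  n <- nrow(segments)
  if (n == 0L) {
    segments$bout <- integer(0)
    return(segments)
  }
  if (is.unsorted(segments$start_s))
    stop("segments must be time-ordered")
  gaps <- segments$start_s[-1L] - segments$end_s[-n]
  segments$bout <- cumsum(c(1L, as.integer(gaps > bout_gap_s)))
  segments
}
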