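#' Sampled waveform
#'
#' The universal carrier of audio, ECG, iEEG and ear-canal data: a numeric
#' vector of samples (nominally full scale, |x| <= 1 for audio) together
#' with its sampling rate and an optional level calibration.
#'
#' @param samples Numeric vector of finite amplitude samples.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param calibration_db_fs Optional dB SPL value corresponding to a
#'   full-scale RMS sinusoid (i.e. a sine of peak amplitude 1). Used by
#'   [band_spl()] to express band levels in dB SPL.
#' @return An object of class `"waveform"`.
#' @export
waveform <- function(samples, rate_hz, calibration_db_fs = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (length(samples) && any(!is.finite(samples)))
    stop("samples must be finite")
  structure(list(samples = samples, rate_hz = rate_hz,
                 calibration_db_fs = calibration_db_fs),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.4f s)%s>\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz,
              if (is.null(x$calibration_db_fs)) "" else
                sprintf(", cal %.1f dB SPL @ FS", x$calibration_db_fs)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param wave A [waveform()].
#' @return Duration in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$rate_hz

as_waveform <- function(x, rate_hz) {
  if (inherits(x, "waveform")) x else waveform(x, rate_hz)
}

#' Read a mono WAV file
#'
#' Reads uncompressed mono RIFF/WAVE files (16-bit integer PCM or 32-bit
#' IEEE float). Integer PCM samples are scaled to [-1, 1).
#'
#' @param path Path to an existing WAV file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("malformed WAV: no data chunk")
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw_fmt[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(raw_fmt[3:4]) * c(1L, 256L)),
        rate_hz      = sum(as.integer(raw_fmt[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw_fmt[15:16]) * c(1L, 256L)))
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt$n_channels != 1L)
        stop("only mono WAV files are supported (file has ",
             fmt$n_channels, " channels)")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        x <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                     endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        x <- readBin(con, "double", n, size = 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding: format ", fmt$audio_format,
             ", ", fmt$bits, " bits (supported: 16-bit PCM, 32-bit float)")
      }
      return(waveform(x, fmt$rate_hz))
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
  }
}

#' Write a mono WAV file
#'
#' @param path Output path.
#' @param wave A [waveform()]; samples should lie in [-1, 1].
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, wave, bits = 16L) {
  stopifnot(inherits(wave, "waveform"))
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  n <- length(wave$samples)
  bytes_per <- bits %/% 8L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  fmt_code <- if (bits == 16L) 1L else 3L
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(wave$rate_hz), con, size = 4L, endian = "little")
  writeBin(as.integer(wave$rate_hz * bytes_per), con, size = 4L,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(wave$samples, 1 - 1 / 32768), -1) * 32768))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(wave$samples, con, size = 4L, endian = "little")
  }
  invisible(path)
}

rms <- function(x) sqrt(mean(x^2))

# Linear-interpolation trapezoid integral over a uniform or irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
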