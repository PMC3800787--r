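# Acoustic stimuli: construction, conditioning and absolute-level calibration.
#
# A stimulus is a calibrated sound-pressure waveform in pascal. Conditioning
# follows the experimental recipe: bandpass 500 Hz-40 kHz, 25-ms raised-cosine
# on/off ramps, 50-ms silent pads, and level setting by the peak of a 20-ms
# sliding RMS window.

#' Acoustic stimulus container
#'
#' A sound-pressure waveform (Pa) with its sampling rate, nominal presentation
#' level and a call label.
#'
#' @param samples numeric vector, sound pressure in Pa.
#' @param rate_hz sampling rate, samples/s (> 0).
#' @param level_db_spl nominal level in dB SPL re 20 uPa, or `NA` if not yet
#'   calibrated.
#' @param label call identifier (e.g. `"TSV"`, `"BH"`, `"BT"`).
#' @return An object of class `acoustic_stimulus`.
#' @export
acoustic_stimulus <- function(samples, rate_hz, level_db_spl = NA_real_,
                              label = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("stimulus has no samples")
  if (!all(is.finite(samples))) stop("stimulus samples must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  structure(
    list(samples = samples, rate_hz = rate_hz,
         level_db_spl = level_db_spl, label = label),
    class = "acoustic_stimulus"
  )
}

#' @export
print.acoustic_stimulus <- function(x, ...) {
  cat(sprintf(
    "<acoustic_stimulus> %s: %.1f ms at %g Hz, level %s dB SPL\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    1000 * length(x$samples) / x$rate_hz, x$rate_hz,
    if (is.na(x$level_db_spl)) "NA" else format(x$level_db_spl)))
  invisible(x)
}

#' Duration of a stimulus in milliseconds
#' @param stim an `acoustic_stimulus`.
#' @return Duration, ms.
#' @export
stimulus_duration_ms <- function(stim) 1000 * length(stim$samples) / stim$rate_hz

# raised-cosine (Hann half-window) on/off ramps, in place on the vector edges
apply_cosine_ramps <- function(x, rate_hz, ramp_ms = 25) {
  n_ramp <- round(ramp_ms / 1000 * rate_hz)
  if (n_ramp < 1L || 2L * n_ramp > length(x)) return(x)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_ramp)))
  x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
  n <- length(x)
  x[(n - n_ramp + 1L):n] <- x[(n - n_ramp + 1L):n] * rev(ramp)
  x
}

#' Condition a raw vocalization waveform
#'
#' Applies the stimulus-preparation chain used for vocalization presentation:
#' zero-phase 4th-order Butterworth bandpass 500 Hz-40 kHz, 25-ms raised-cosine
#' onset/offset ramps, then 50 ms of silence prepended and appended, so the
#' output is 100 ms longer than the input. When the sampling rate cannot
#' represent the 40-kHz band edge it is clipped to 0.95 x Nyquist with a
#' warning.
#'
#' @param raw_waveform numeric pressure series (Pa).
#' @param rate_hz sampling rate; must be at least 8 kHz.
#' @param label optional call label carried on the result.
#' @param band_hz bandpass edges, Hz (default `c(500, 40000)`).
#' @return An [acoustic_stimulus()] with 50-ms silent pads.
#' @export
prepare_vocalization <- function(raw_waveform, rate_hz, label = "",
                                 band_hz = c(500, 40000)) {
  raw_waveform <- as.numeric(raw_waveform)
  if (length(raw_waveform) == 0L) stop("empty input waveform")
  if (rate_hz < 8000) stop("sampling rate below 8 kHz cannot represent the call band")
  if (length(raw_waveform) <= 0.05 * rate_hz)
    stop("waveform must be longer than 50 ms")
  nyq <- rate_hz / 2
  hi <- band_hz[2]
  if (hi >= nyq) {
    hi <- 0.95 * nyq
    warning(sprintf(
      "upper band edge clipped to %.0f Hz (0.95 x Nyquist at rate %g Hz)",
      hi, rate_hz))
  }
  bp <- signal::butter(4, c(band_hz[1], hi) / nyq, type = "pass")
  x <- signal::filtfilt(bp, raw_waveform)
  x <- apply_cosine_ramps(x, rate_hz, ramp_ms = 25)
  n_pad <- round(0.05 * rate_hz)
  x <- c(numeric(n_pad), x, numeric(n_pad))
  acoustic_stimulus(x, rate_hz, level_db_spl = NA_real_, label = label)
}

#' Sliding RMS of a pressure series
#'
#' RMS over a sliding window advanced one sample at a time.
#'
#' @param x numeric series.
#' @param rate_hz sampling rate.
#' @param window_ms window length, ms (default 20).
#' @return Vector of RMS values, one per window position.
#' @export
sliding_rms <- function(x, rate_hz, window_ms = 20) {
  n_win <- round(window_ms / 1000 * rate_hz)
  if (n_win > length(x)) n_win <- length(x)
  cs <- cumsum(c(0, x^2))
  sq <- (cs[(n_win + 1L):length(cs)] - cs[seq_len(length(x) - n_win + 1L)]) / n_win
  sqrt(pmax(sq, 0))
}

#' Calibrate a stimulus to a target sound level
#'
#' Scales the waveform by one constant so that the peak of a 20-ms sliding RMS
#' window equals the pressure corresponding to `target_db_spl` (re 20 uPa),
#' matching how presentation levels were defined experimentally.
#'
#' @param stim an [acoustic_stimulus()].
#' @param target_db_spl target level, dB SPL.
#' @param window_ms RMS window, ms.
#' @return The scaled stimulus with `level_db_spl` set.
#' @export
calibrate_level <- function(stim, target_db_spl, window_ms = 20) {
  stopifnot(inherits(stim, "acoustic_stimulus"))
  peak_rms <- max(sliding_rms(stim$samples, stim$rate_hz, window_ms))
  if (peak_rms <= 0) stop("all-zero stimulus: level is undefined")
  scale <- db_spl_to_pa(target_db_spl) / peak_rms
  out <- stim
  out$samples <- stim$samples * scale
  out$level_db_spl <- target_db_spl
  out
}

# ---------------------------------------------------------------------------
# WAV I/O: minimal RIFF/WAVE support (PCM 16/24-bit and IEEE float32, mono or
# the first channel of multichannel files).

#' Read a WAV file
#'
#' Supports PCM 16/24-bit and IEEE float32. Multichannel files return the
#' first channel. Integer formats are scaled to \[-1, 1).
#'
#' @param path file path.
#' @return List with `samples` (numeric) and `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate_hz      = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt or data chunk")
  bytes <- fmt$bits %/% 8L
  n_tot <- length(data_raw) %/% bytes
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n_tot, size = 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_tot, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n_tot * 3L)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop("unsupported WAV format (need PCM16/24 or float32)")
  }
  if (fmt$n_channels > 1L)
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  list(samples = x, rate_hz = fmt$rate_hz)
}

#' Write a WAV file
#'
#' @param samples numeric vector. For `format = "float32"` values are written
#'   as-is; for `"pcm16"` they must lie in \[-1, 1\].
#' @param rate_hz sampling rate.
#' @param path output path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate_hz, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (format == "float32") {
    bytes <- 4L; audio_fmt <- 3L; bits <- 32L
  } else {
    bytes <- 2L; audio_fmt <- 1L; bits <- 16L
  }
  data_sz <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz * bytes), con, size = 4, endian = "little")
  writeBin(bytes, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Save / load a stimulus as WAV plus JSON sidecar
#'
#' The waveform goes to `<path>.wav` (float32, pressure in Pa) and the
#' metadata (rate, level, label) to `<path>.json`.
#'
#' @param stim an [acoustic_stimulus()].
#' @param path base path without extension.
#' @return Base path (write) or the stimulus (read), invisibly/visibly.
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "acoustic_stimulus"))
  write_wav(stim$samples, stim$rate_hz, paste0(path, ".wav"))
  jsonlite::write_json(
    list(rate_hz = stim$rate_hz, level_db_spl = stim$level_db_spl,
         label = stim$label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  wav <- read_wav(paste0(path, ".wav"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  acoustic_stimulus(wav$samples, wav$rate_hz,
                    level_db_spl = if (is.null(meta$level_db_spl)) NA_real_
                                   else as.numeric(meta$level_db_spl),
                    label = if (is.null(meta$label)) "" else meta$label)
}
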