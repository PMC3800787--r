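# Envelope extraction: Hilbert envelope of a DRNL channel, 1-ms binning,
# 10-ms sliding-average smoothing and max-normalization. The smoothed,
# normalized trace is the quantity every correlation analysis consumes.

#' Envelope trace container
#'
#' A non-negative envelope at 1-ms resolution for one best-frequency channel.
#'
#' @param bf_hz channel best frequency, Hz.
#' @param values numeric envelope values at 1-ms bins.
#' @param t0_ms time of the first bin relative to stimulus onset, ms.
#' @param normalized logical: has the trace been max-normalized to 1?
#' @return An `envelope_trace` object.
#' @export
envelope_trace <- function(bf_hz, values, t0_ms = 0, normalized = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("envelope values must be finite")
  if (any(values < 0)) stop("envelope values must be non-negative")
  if (isTRUE(normalized) && abs(max(values) - 1) > 1e-12)
    stop("normalized trace must have max exactly 1")
  structure(list(bf_hz = bf_hz, values = values, t0_ms = t0_ms,
                 normalized = isTRUE(normalized)),
            class = "envelope_trace")
}

#' @export
print.envelope_trace <- function(x, ...) {
  cat(sprintf("<envelope_trace> BF %.0f Hz, %d x 1-ms bins from t0=%g ms%s\n",
              x$bf_hz, length(x$values), x$t0_ms,
              if (x$normalized) ", max-normalized" else ""))
  invisible(x)
}

#' Hilbert envelope of a band-limited signal
#'
#' Magnitude of the analytic signal, computed by FFT half-spectrum doubling.
#'
#' @param x numeric series, or a `bm_response`.
#' @return Non-negative envelope series at the input rate.
#' @export
hilbert_envelope <- function(x) {
  if (inherits(x, "bm_response")) x <- x$samples
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("input must be finite")
  n <- length(x)
  if (n == 0L) stop("empty input")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Downsample an audio-rate series to 1-ms bins
#'
#' Bin `k` is the mean of all samples whose time falls in `[k, k+1)` ms;
#' averaging within the bin acts as the anti-aliasing step and matches PSTH
#' binning semantics. Output length is the floor of the duration in ms.
#'
#' @param x numeric series at audio rate.
#' @param rate_hz sampling rate (>= 1000).
#' @return Numeric vector with one value per 1-ms bin.
#' @export
downsample_1ms <- function(x, rate_hz) {
  if (rate_hz < 1000) stop("rate_hz must be at least 1000")
  n <- length(x)
  n_bins <- floor(n / rate_hz * 1000)
  if (n_bins < 1L) stop("series shorter than 1 ms")
  bin <- floor((seq_len(n) - 1) / rate_hz * 1000)
  keep <- bin < n_bins
  as.numeric(tapply(x[keep], bin[keep], mean))
}

#' 10-ms sliding-average smoothing of a 1-ms series
#'
#' Centred boxcar over `width_ms` bins; edge windows shrink to the available
#' bins. A 10-bin boxcar passes envelope fluctuations up to roughly 100 Hz
#' and nulls a 100-Hz modulation exactly.
#'
#' @param x numeric 1-ms series (length >= `width_ms`).
#' @param width_ms window width in bins/ms (default 10).
#' @return Smoothed series, same length.
#' @export
smooth_10ms <- function(x, width_ms = 10) {
  if (length(x) < width_ms) stop("series shorter than the smoothing window")
  as.numeric(zoo::rollapply(zoo::zoo(x), width = width_ms, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Normalize a series by its maximum
#'
#' Divides by `max(x)`; the maximum of the result is exactly 1. The maximum
#' (not the absolute maximum) is used, so negative excursions are preserved.
#'
#' @param x numeric series with `max(x) > 0`.
#' @return `x / max(x)`.
#' @export
normalize_max <- function(x) {
  m <- max(x)
  if (!is.finite(m) || m <= 0) stop("cannot normalize: maximum is not positive")
  x / m
}

#' Frequency-specific envelope of a stimulus (the "DRNL output")
#'
#' Full composition for one channel: middle ear, DRNL channel, Hilbert
#' envelope, 1-ms binning, 10-ms smoothing, max-normalization.
#'
#' @param stim an [acoustic_stimulus()].
#' @param bf_hz channel best frequency, Hz.
#' @param coefs DRNL coefficient set (default [drnl_default_coefs()]).
#' @param variant `"full"`, `"linear"` or `"nonlinear"` path selection.
#' @param smooth apply the 10-ms smoothing (default TRUE).
#' @param normalize apply max-normalization (default TRUE; disable for
#'   population dB-FS panels).
#' @return An [envelope_trace()].
#' @export
drnl_output <- function(stim, bf_hz, coefs = drnl_default_coefs(),
                        variant = "full", smooth = TRUE, normalize = TRUE) {
  bm <- drnl_channel(middle_ear_filter(stim),
                     drnl_params(bf_hz, stim$rate_hz, coefs),
                     variant = variant)
  env <- hilbert_envelope(bm)
  env <- downsample_1ms(env, stim$rate_hz)
  if (smooth) env <- smooth_10ms(env)
  if (normalize) env <- normalize_max(env)
  envelope_trace(bf_hz, env, t0_ms = 0, normalized = normalize)
}

#' Write / read an envelope trace as CSV
#'
#' Two columns `t_ms, value`; the header comment line carries BF and
#' provenance fields.
#'
#' @param env an [envelope_trace()].
#' @param path output path.
#' @param label,level_db_spl optional provenance stored in the header.
#' @return `path` (write); an `envelope_trace` (read).
#' @export
write_envelope_csv <- function(env, path, label = "", level_db_spl = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bf_hz=%g t0_ms=%g normalized=%s label=%s level_db_spl=%s",
                     env$bf_hz, env$t0_ms, env$normalized, label,
                     format(level_db_spl)), con)
  writeLines("t_ms,value", con)
  t_ms <- env$t0_ms + seq_along(env$values) - 1
  writeLines(paste(t_ms, format(env$values, digits = 15), sep = ","), con)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  fields <- regmatches(hdr, gregexpr("[a-z0-9_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(fields, "=")
  meta <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  d <- read.csv(path, skip = 1L)
  envelope_trace(as.numeric(meta$bf_hz), d$value,
                 t0_ms = as.numeric(meta$t0_ms),
                 normalized = identical(meta$normalized, "TRUE"))
}
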