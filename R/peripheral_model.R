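# Peripheral ear model: middle-ear filter cascade and the dual-resonance
# non-linear (DRNL) cochlear filterbank.
#
# The middle ear is a cascade of two causal Butterworth bandpasses (2nd order
# 4-25 kHz, 3rd order 700 Hz-30 kHz, both unity passband gain) followed by a
# pressure-to-stapes-velocity scalar of 1.4e-10 (m/s)/Pa. Each DRNL channel
# sums a linear path (gain -> 3 first-order gammatones -> 4x 2nd-order
# Butterworth lowpass) and a compressive non-linear path (3 gammatones ->
# broken-stick -> 3 gammatones -> 4x 1st-order Butterworth lowpass).

STAPES_SCALE <- 1.4e-10  # (m/s) per Pa after middle-ear filtering

#' Middle-ear filter: sound pressure to stapes velocity
#'
#' Passes the pressure waveform through a 2nd-order Butterworth bandpass
#' (4-25 kHz) cascaded with a 3rd-order Butterworth bandpass (700 Hz-30 kHz),
#' both causal with unity passband gain, then scales by 1.4e-10 to convert
#' pascal to stapes velocity in m/s. Band edges above Nyquist are clipped to
#' 0.95 x Nyquist with a warning (rates of at least 60 kHz avoid this).
#'
#' @param stim an [acoustic_stimulus()].
#' @return A `stapes_velocity` object (samples in m/s, plus `rate_hz`).
#' @export
middle_ear_filter <- function(stim) {
  stopifnot(inherits(stim, "acoustic_stimulus"))
  fs <- stim$rate_hz
  nyq <- fs / 2
  clip <- function(edge) {
    if (edge >= nyq) {
      warning(sprintf("middle-ear band edge %.0f Hz clipped to 0.95 x Nyquist (rate %g Hz)",
                      edge, fs))
      0.95 * nyq
    } else edge
  }
  b1 <- signal::butter(2, c(4000, clip(25000)) / nyq, type = "pass")
  b2 <- signal::butter(3, c(700, clip(30000)) / nyq, type = "pass")
  x <- signal::filter(b1, stim$samples)
  x <- signal::filter(b2, x)
  structure(list(samples = STAPES_SCALE * as.numeric(x), rate_hz = fs),
            class = "stapes_velocity")
}

#' @export
print.stapes_velocity <- function(x, ...) {
  cat(sprintf("<stapes_velocity> %d samples at %g Hz, peak %.3g m/s\n",
              length(x$samples), x$rate_hz, max(abs(x$samples))))
  invisible(x)
}

#' Default DRNL coefficient set (guinea-pig style, SI units)
#'
#' Per-channel DRNL parameters are generated from best frequency (BF) by
#' log-linear laws `log10(p) = p0 + m * log10(BF)`. The shipped set follows
#' the guinea-pig DRNL parametrization family, with the broken-stick `b`
#' coefficient converted to SI stapes velocity (pressure in Pa through the
#' 1.4e-10 stapes scalar), which places the compression knee of a BF tone
#' near 40 dB SPL. The compression exponent `nu` is a fixed 0.1. All values
#' can be overridden from a YAML file (see [read_drnl_coefs()]).
#'
#' @return A named list of `c(p0, m)` pairs plus scalars `nu` and `lin_gain`
#'   coefficients; class `drnl_coefs`.
#' @export
drnl_default_coefs <- function() {
  structure(list(
    lin_cf     = c(p0 = 0.339, m = 0.895),   # linear-path gammatone centre, Hz
    lin_bw     = c(p0 = 1.300, m = 0.530),   # linear-path gammatone bandwidth, Hz
    lin_lp     = c(p0 = 0.339, m = 0.895),   # linear-path lowpass cutoff, Hz
    lin_gain   = c(p0 = 5.680, m = -0.970),  # linear-path gain, dimensionless
    nl_cf      = c(p0 = 0.000, m = 1.000),   # non-linear gammatone centre = BF
    nl_bw      = c(p0 = 0.800, m = 0.580),   # non-linear gammatone bandwidth, Hz
    nl_lp      = c(p0 = 0.000, m = 1.000),   # non-linear lowpass cutoff = BF
    bs_a       = c(p0 = 1.870, m = 0.450),   # broken-stick linear branch gain
    bs_b       = c(p0 = -11.050, m = 0.875), # broken-stick compressive branch gain
    bs_nu      = 0.1                         # compression exponent
  ), class = "drnl_coefs")
}

#' Read DRNL coefficients from a YAML file
#'
#' The schema mirrors [drnl_default_coefs()]: each log-linear parameter is a
#' mapping with keys `p0` and `m`; `bs_nu` is a scalar in (0, 1]. Missing
#' entries fall back to the shipped defaults.
#'
#' @param path YAML file path.
#' @return A `drnl_coefs` object.
#' @export
read_drnl_coefs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- drnl_default_coefs()
  for (nm in names(raw)) {
    if (!nm %in% names(out)) stop("unknown DRNL coefficient: ", nm)
    if (nm == "bs_nu") {
      out$bs_nu <- as.numeric(raw[[nm]])
    } else {
      if (is.null(raw[[nm]]$p0) || is.null(raw[[nm]]$m))
        stop("coefficient ", nm, " needs fields p0 and m")
      out[[nm]] <- c(p0 = as.numeric(raw[[nm]]$p0), m = as.numeric(raw[[nm]]$m))
    }
  }
  validate_drnl_coefs(out)
  out
}

validate_drnl_coefs <- function(coefs) {
  need <- c("lin_cf", "lin_bw", "lin_lp", "lin_gain", "nl_cf", "nl_bw",
            "nl_lp", "bs_a", "bs_b", "bs_nu")
  if (!all(need %in% names(coefs))) stop("incomplete DRNL coefficient set")
  if (!(coefs$bs_nu > 0 && coefs$bs_nu <= 1))
    stop("bs_nu must lie in (0, 1]")
  invisible(coefs)
}

loglin <- function(co, bf_hz) 10^(co["p0"] + co["m"] * log10(bf_hz))

#' Per-channel DRNL parameters for one best frequency
#'
#' Evaluates the log-linear coefficient laws at `bf_hz` and validates the
#' result against the sampling rate.
#'
#' @param bf_hz channel best frequency, Hz.
#' @param rate_hz sampling rate the channel will run at.
#' @param coefs a `drnl_coefs` object (default [drnl_default_coefs()]).
#' @return A `drnl_params` object.
#' @export
drnl_params <- function(bf_hz, rate_hz, coefs = drnl_default_coefs()) {
  validate_drnl_coefs(coefs)
  if (bf_hz <= 0) stop("bf_hz must be positive")
  if (bf_hz >= rate_hz / 2) stop("bf_hz at or above Nyquist")
  p <- list(
    bf_hz            = bf_hz,
    lin_gain         = unname(loglin(coefs$lin_gain, bf_hz)),
    lin_gt_cf_hz     = unname(loglin(coefs$lin_cf, bf_hz)),
    lin_gt_bw_hz     = unname(loglin(coefs$lin_bw, bf_hz)),
    lin_lp_cutoff_hz = unname(loglin(coefs$lin_lp, bf_hz)),
    nl_gt_cf_hz      = unname(loglin(coefs$nl_cf, bf_hz)),
    nl_gt_bw_hz      = unname(loglin(coefs$nl_bw, bf_hz)),
    nl_lp_cutoff_hz  = unname(loglin(coefs$nl_lp, bf_hz)),
    bs_a             = unname(loglin(coefs$bs_a, bf_hz)),
    bs_b             = unname(loglin(coefs$bs_b, bf_hz)),
    bs_nu            = coefs$bs_nu,
    rate_hz          = rate_hz
  )
  freqs <- c(p$lin_gt_cf_hz, p$lin_lp_cutoff_hz, p$nl_gt_cf_hz, p$nl_lp_cutoff_hz)
  if (any(freqs >= rate_hz / 2))
    stop("a DRNL centre/cutoff frequency reaches Nyquist; increase the rate")
  if (p$bs_a <= 0 || p$bs_b <= 0) stop("broken-stick gains must be positive")
  structure(p, class = "drnl_params")
}

#' @export
print.drnl_params <- function(x, ...) {
  cat(sprintf(
    "<drnl_params> BF %.0f Hz | lin: g=%.3g cf=%.0f bw=%.0f lp=%.0f | nl: cf=%.0f bw=%.0f lp=%.0f a=%.3g b=%.3g nu=%.2f\n",
    x$bf_hz, x$lin_gain, x$lin_gt_cf_hz, x$lin_gt_bw_hz, x$lin_lp_cutoff_hz,
    x$nl_gt_cf_hz, x$nl_gt_bw_hz, x$nl_lp_cutoff_hz, x$bs_a, x$bs_b, x$bs_nu))
  invisible(x)
}

#' Broken-stick compressive non-linearity
#'
#' `y = sign(x) * min(a|x|, b|x|^nu)`: linear growth for small inputs,
#' compressive power-law growth beyond the knee. Odd-symmetric, continuous and
#' non-decreasing for `nu` in (0, 1].
#'
#' @param x input sample(s).
#' @param params a `drnl_params` object, or a list with `bs_a`, `bs_b`, `bs_nu`.
#' @return Transformed sample(s).
#' @export
broken_stick <- function(x, params) {
  a <- params$bs_a; b <- params$bs_b; nu <- params$bs_nu
  ax <- abs(x)
  sign(x) * pmin(a * ax, b * ax^nu)
}

#' Gammatone resonator cascade
#'
#' Cascade of `n` first-order gammatone filters (impulse response
#' `exp(-2*pi*bw*t) * cos(2*pi*cf*t)`), realized as complex one-pole sections
#' with unit gain at the centre frequency.
#'
#' @param x numeric input series.
#' @param cf_hz centre frequency, Hz.
#' @param bw_hz bandwidth parameter, Hz.
#' @param rate_hz sampling rate.
#' @param n number of cascaded sections (default 3).
#' @return Filtered series, same length as `x`.
#' @export
gammatone_cascade <- function(x, cf_hz, bw_hz, rate_hz, n = 3L) {
  stopifnot(cf_hz > 0, cf_hz < rate_hz / 2, bw_hz > 0)
  gammatone_cascade_cpp(as.numeric(x), cf_hz, bw_hz, rate_hz, as.integer(n))
}

# causal Butterworth lowpass applied k times
butter_lp_cascade <- function(x, cutoff_hz, rate_hz, order, k) {
  bl <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  for (i in seq_len(k)) x <- as.numeric(signal::filter(bl, x))
  x
}

#' One DRNL channel: stapes velocity to basilar-membrane velocity
#'
#' Runs the linear and non-linear paths and sums them (or returns a single
#' path via `variant`). The linear path is a linear time-invariant map: gain,
#' three first-order gammatones, then four 2nd-order Butterworth lowpasses.
#' The non-linear path applies three gammatones, the broken-stick compressor,
#' three more gammatones, then four 1st-order Butterworth lowpasses.
#'
#' @param stapes a `stapes_velocity` object from [middle_ear_filter()].
#' @param params a `drnl_params` object for the channel.
#' @param variant `"full"` (sum, default), `"linear"` or `"nonlinear"`.
#' @return A `bm_response` object (`bf_hz`, `samples` in m/s, `rate_hz`).
#' @export
drnl_channel <- function(stapes, params,
                         variant = c("full", "linear", "nonlinear")) {
  stopifnot(inherits(stapes, "stapes_velocity"),
            inherits(params, "drnl_params"))
  variant <- match.arg(variant)
  if (params$bf_hz >= stapes$rate_hz / 2) stop("bf_hz at or above Nyquist")
  fs <- stapes$rate_hz
  x <- stapes$samples
  out <- 0
  if (variant %in% c("full", "linear")) {
    lin <- params$lin_gain * x
    lin <- gammatone_cascade(lin, params$lin_gt_cf_hz, params$lin_gt_bw_hz, fs, 3L)
    lin <- butter_lp_cascade(lin, params$lin_lp_cutoff_hz, fs, order = 2, k = 4)
    out <- out + lin
  }
  if (variant %in% c("full", "nonlinear")) {
    nl <- gammatone_cascade(x, params$nl_gt_cf_hz, params$nl_gt_bw_hz, fs, 3L)
    nl <- broken_stick(nl, params)
    nl <- gammatone_cascade(nl, params$nl_gt_cf_hz, params$nl_gt_bw_hz, fs, 3L)
    nl <- butter_lp_cascade(nl, params$nl_lp_cutoff_hz, fs, order = 1, k = 4)
    out <- out + nl
  }
  structure(list(bf_hz = params$bf_hz, samples = out, rate_hz = fs),
            class = "bm_response")
}

#' @export
print.bm_response <- function(x, ...) {
  cat(sprintf("<bm_response> BF %.0f Hz, %d samples at %g Hz\n",
              x$bf_hz, length(x$samples), x$rate_hz))
  invisible(x)
}

#' DRNL filterbank over a set of best frequencies
#'
#' Runs [middle_ear_filter()] once, then an independent [drnl_channel()] per
#' requested BF.
#'
#' @param stim an [acoustic_stimulus()].
#' @param bfs numeric vector of best frequencies, Hz.
#' @param coefs DRNL coefficient set (default [drnl_default_coefs()]).
#' @param variant passed to [drnl_channel()].
#' @return List of `bm_response`, one per BF, in input order.
#' @export
drnl_filterbank <- function(stim, bfs, coefs = drnl_default_coefs(),
                            variant = "full") {
  if (length(bfs) == 0L) stop("empty best-frequency list")
  stapes <- middle_ear_filter(stim)
  lapply(bfs, function(bf) {
    drnl_channel(stapes, drnl_params(bf, stim$rate_hz, coefs), variant = variant)
  })
}
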