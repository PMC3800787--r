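# Neural responses: spike detection from extracellular traces, driven PSTHs,
# frequency response maps (FRMs) and best-frequency (BF) estimation.
#
# Driven PSTH = total spikes across trials per 1-ms bin minus the mean
# spontaneous count per bin scaled to the driven trial count; bins may go
# negative. FRM driven rate uses a 5-65 ms post-onset window. BF is the
# rate-weighted log2-frequency centroid at 10 dB above threshold.

#' Spike train set
#'
#' Per-trial spike times for one recording site under one condition.
#'
#' @param site_id site identifier.
#' @param condition condition label (stimulus + level, or `"spontaneous"`).
#' @param trials list of numeric vectors of spike times, ms from the start of
#'   the recording window; each is sorted and non-negative.
#' @return A `spike_train_set` object.
#' @export
spike_train_set <- function(site_id, condition, trials) {
  if (!is.list(trials) || length(trials) < 1L)
    stop("trials must be a non-empty list of spike-time vectors")
  trials <- lapply(trials, function(tr) {
    tr <- as.numeric(tr)
    if (any(tr < 0)) stop("spike times must be non-negative")
    sort(tr)
  })
  structure(list(site_id = site_id, condition = condition,
                 trials = trials, n_trials = length(trials)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> site %s, condition %s: %d trials, %d spikes\n",
              format(x$site_id), format(x$condition), x$n_trials,
              sum(lengths(x$trials))))
  invisible(x)
}

#' Read / write spike tables
#'
#' CSV with columns `site_id, condition, trial, spike_time_ms`. Reading
#' returns one [spike_train_set()] per (site, condition); trials with no
#' spikes must still appear (with `spike_time_ms` `NA`) to be counted.
#'
#' @param sets list of `spike_train_set` (write) / `path` file path.
#' @param path file path.
#' @return `path` (write); named list of `spike_train_set` (read).
#' @export
write_spike_csv <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    do.call(rbind, lapply(seq_along(s$trials), function(i) {
      st <- s$trials[[i]]
      data.frame(site_id = s$site_id, condition = s$condition, trial = i,
                 spike_time_ms = if (length(st)) st else NA_real_)
    }))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  d <- read.csv(path)
  need <- c("site_id", "condition", "trial", "spike_time_ms")
  if (!all(need %in% names(d))) stop("spike table needs columns: ",
                                     paste(need, collapse = ", "))
  key <- interaction(d$site_id, d$condition, drop = TRUE)
  lapply(split(d, key), function(g) {
    trials <- split(g$spike_time_ms, g$trial)
    trials <- lapply(trials, function(v) v[!is.na(v)])
    spike_train_set(g$site_id[1], g$condition[1], trials)
  })
}

#' Detect multi-unit spikes in an extracellular trace
#'
#' The trace is bandpass filtered 300-3000 Hz (2nd-order Butterworth,
#' zero-phase so spike times are not lag-shifted), the background noise SD is
#' estimated robustly as `median(|x|)/0.6745` unless supplied, and local
#' minima below `-threshold_sd * noise SD` are reported once each with a 1-ms
#' refractory lockout. Only negative peaks count as spikes.
#'
#' @param trace numeric extracellular series.
#' @param rate_hz sampling rate (>= 8 kHz).
#' @param noise_sd background-noise SD of the filtered trace; estimated
#'   robustly when `NULL`.
#' @param threshold_sd threshold multiplier (default 3.5).
#' @param band_hz detection bandpass edges (default `c(300, 3000)`).
#' @return Numeric vector of spike times, ms (at the trough sample).
#' @export
detect_spikes <- function(trace, rate_hz, noise_sd = NULL, threshold_sd = 3.5,
                          band_hz = c(300, 3000)) {
  trace <- as.numeric(trace)
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  if (rate_hz < 8000) stop("rate_hz must be at least 8 kHz")
  if (length(trace) <= 0.01 * rate_hz) stop("trace must be longer than 10 ms")
  bp <- signal::butter(2, band_hz / (rate_hz / 2), type = "pass")
  x <- signal::filtfilt(bp, trace)
  if (is.null(noise_sd)) noise_sd <- median(abs(x)) / 0.6745
  thr <- -threshold_sd * noise_sd
  n <- length(x)
  is_min <- c(FALSE, x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] < x[3:n], FALSE)
  cand <- which(is_min & x < thr)
  if (length(cand) == 0L) return(numeric(0))
  lock <- rate_hz / 1000  # 1-ms refractory lockout, in samples
  keep <- numeric(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= lock) {
      keep <- c(keep, i)
      last <- i
    }
  }
  (keep - 1) / rate_hz * 1000
}

# spike counts per 1-ms bin, summed across trials
bin_spikes <- function(trials, duration_ms) {
  counts <- numeric(duration_ms)
  for (tr in trials) {
    tr <- tr[tr >= 0 & tr < duration_ms]
    if (length(tr)) {
      tb <- tabulate(floor(tr) + 1L, nbins = duration_ms)
      counts <- counts + tb
    }
  }
  counts
}

#' Driven post-stimulus time histogram
#'
#' Bins driven spikes at 1 ms, summed across trials, and subtracts the mean
#' spontaneous count per bin scaled to the driven trial count. Bins may be
#' negative after subtraction.
#'
#' @param driven a [spike_train_set()] of stimulus trials.
#' @param spont a [spike_train_set()] of spontaneous trials, or `NULL` to skip
#'   subtraction.
#' @param duration_ms PSTH length, ms (integer number of 1-ms bins).
#' @param bf_hz optional best frequency carried as metadata.
#' @return A `psth` object with fields `bins`, `site_id`, `bf_hz`, `t0_ms`,
#'   `n_trials`, `normalized`.
#' @export
build_psth <- function(driven, spont = NULL, duration_ms, bf_hz = NA_real_) {
  stopifnot(inherits(driven, "spike_train_set"))
  duration_ms <- as.integer(duration_ms)
  if (duration_ms < 1L) stop("duration_ms must be at least 1")
  bins <- bin_spikes(driven$trials, duration_ms)
  if (!is.null(spont)) {
    stopifnot(inherits(spont, "spike_train_set"))
    spont_mean <- bin_spikes(spont$trials, duration_ms) / spont$n_trials
    bins <- bins - spont_mean * driven$n_trials
  }
  structure(list(site_id = driven$site_id, bf_hz = bf_hz, bins = bins,
                 t0_ms = 0, n_trials = driven$n_trials, normalized = FALSE),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> site %s%s: %d x 1-ms bins, %d trials%s\n",
              format(x$site_id),
              if (is.na(x$bf_hz)) "" else sprintf(" (BF %.0f Hz)", x$bf_hz),
              length(x$bins), x$n_trials,
              if (x$normalized) ", max-normalized" else ""))
  invisible(x)
}

#' Smooth and max-normalize a PSTH for correlation analysis
#'
#' Applies the same 10-ms sliding average used for envelope traces, then
#' max-normalization.
#'
#' @param psth a `psth` object.
#' @param smooth apply [smooth_10ms()] (default TRUE).
#' @param normalize apply [normalize_max()] (default TRUE).
#' @return The transformed `psth`.
#' @export
condition_psth <- function(psth, smooth = TRUE, normalize = TRUE) {
  stopifnot(inherits(psth, "psth"))
  if (smooth) psth$bins <- smooth_10ms(psth$bins)
  if (normalize) {
    psth$bins <- normalize_max(psth$bins)
    psth$normalized <- TRUE
  }
  psth
}

#' Frequency response map from tone responses
#'
#' Driven spike rate per (frequency, level): spikes inside the 5-65 ms
#' post-onset window, minus the spontaneous expectation for a window of the
#' same length, divided by `n_trials * window`. Missing cells become `NaN`
#' with a message.
#'
#' @param tone_sets list of [spike_train_set()] whose `condition` labels have
#'   the form `"<freq_hz>@<level_db>"`, or a data frame with columns
#'   `freq_hz, level_db, trial, spike_time_ms`.
#' @param spont a [spike_train_set()] of spontaneous activity, or `NULL`; its
#'   rate is estimated over `spont_duration_ms`.
#' @param window_ms analysis window, ms (default `c(5, 65)`).
#' @param spont_duration_ms duration of each spontaneous trial, ms.
#' @return A `frequency_response_map`: `freqs_hz`, `levels_db_spl`,
#'   `driven_rate` matrix (freq x level, spikes/s).
#' @export
compute_frm <- function(tone_sets, spont = NULL, window_ms = c(5, 65),
                        spont_duration_ms = 200) {
  if (is.data.frame(tone_sets)) {
    need <- c("freq_hz", "level_db", "trial", "spike_time_ms")
    if (!all(need %in% names(tone_sets)))
      stop("tone-response table needs columns: ", paste(need, collapse = ", "))
    key <- interaction(tone_sets$freq_hz, tone_sets$level_db, drop = TRUE)
    tone_sets <- lapply(split(tone_sets, key), function(g) {
      trials <- lapply(split(g$spike_time_ms, g$trial), function(v) v[!is.na(v)])
      spike_train_set("frm", sprintf("%g@%g", g$freq_hz[1], g$level_db[1]),
                      trials)
    })
  }
  parse_cond <- function(s) as.numeric(strsplit(s, "@", fixed = TRUE)[[1]])
  fl <- t(vapply(tone_sets, function(s) parse_cond(as.character(s$condition)),
                 numeric(2)))
  freqs <- sort(unique(fl[, 1]))
  levels <- sort(unique(fl[, 2]))
  if (length(freqs) < 2L || length(levels) < 2L)
    stop("need at least 2 frequencies and 2 levels")
  win_s <- diff(window_ms) / 1000
  spont_rate <- if (is.null(spont)) 0 else
    sum(lengths(spont$trials)) / (spont$n_trials * spont_duration_ms / 1000)
  rate <- matrix(NaN, length(freqs), length(levels),
                 dimnames = list(format(freqs), format(levels)))
  for (i in seq_along(tone_sets)) {
    s <- tone_sets[[i]]
    fi <- match(fl[i, 1], freqs); li <- match(fl[i, 2], levels)
    n_in <- sum(vapply(s$trials, function(tr)
      sum(tr >= window_ms[1] & tr < window_ms[2]), numeric(1)))
    rate[fi, li] <- n_in / (s$n_trials * win_s) - spont_rate
  }
  if (any(is.nan(rate)))
    message(sum(is.nan(rate)), " missing frequency-level cells filled with NaN")
  structure(list(freqs_hz = freqs, levels_db_spl = levels, driven_rate = rate),
            class = "frequency_response_map")
}

#' @export
print.frequency_response_map <- function(x, ...) {
  cat(sprintf("<frequency_response_map> %d freqs x %d levels, peak %.1f spikes/s\n",
              length(x$freqs_hz), length(x$levels_db_spl),
              max(x$driven_rate, na.rm = TRUE)))
  invisible(x)
}

#' Write / read an FRM as a CSV matrix (frequency rows, level columns)
#' @param frm a `frequency_response_map` / `path` file path.
#' @param path file path.
#' @return `path` (write); `frequency_response_map` (read).
#' @export
write_frm_csv <- function(frm, path) {
  d <- data.frame(freq_hz = frm$freqs_hz, frm$driven_rate, check.names = FALSE)
  names(d)[-1] <- format(frm$levels_db_spl)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frm_csv
#' @export
read_frm_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  structure(list(freqs_hz = d$freq_hz,
                 levels_db_spl = as.numeric(names(d)[-1]),
                 driven_rate = as.matrix(d[, -1, drop = FALSE])),
            class = "frequency_response_map")
}

#' Best frequency from a frequency response map
#'
#' Threshold level = lowest level whose maximum driven rate reaches
#' `criterion_frac` of the global map maximum (an automated stand-in for the
#' visually determined threshold). BF is then the rate-weighted centroid in
#' log2 frequency at 10 dB above that threshold. Centroid weights are the
#' driven rates floored at `weight_floor_frac` of that row's maximum and
#' clipped at zero: off-peak cells of a spontaneous-subtracted map carry
#' zero-mean Poisson noise, and summing every positive cell across a
#' 6.6-octave grid would bias the centroid toward the grid centre. The floor
#' is proportional to the row maximum, so the estimate stays invariant to
#' rate scaling; `weight_floor_frac = 0` recovers plain clipping at zero.
#'
#' @param frm a `frequency_response_map`.
#' @param criterion_frac fraction of the global maximum defining threshold
#'   (default 0.2).
#' @param step_db level step to add above threshold (default 10).
#' @param weight_floor_frac fraction of the target row's maximum subtracted
#'   from the centroid weights (default 0.2).
#' @param log2_centroid compute the centroid in log2 frequency (default TRUE;
#'   set FALSE for a linear-frequency centroid sensitivity check).
#' @return Best frequency, Hz.
#' @export
estimate_bf <- function(frm, criterion_frac = 0.2, step_db = 10,
                        weight_floor_frac = 0.2, log2_centroid = TRUE) {
  stopifnot(inherits(frm, "frequency_response_map"))
  m <- frm$driven_rate
  m[is.na(m)] <- 0
  # a light 3-point average across frequency stabilizes the threshold
  # estimate against per-cell Poisson noise (centroid weights stay raw)
  n_f <- nrow(m)
  msm <- (m[c(1, seq_len(n_f - 1)), , drop = FALSE] + m +
            m[c(seq_len(n_f - 1) + 1, n_f), , drop = FALSE]) / 3
  global_max <- max(msm)
  if (!is.finite(global_max) || global_max <= 0) stop("untuned site")
  # on maps large enough to estimate a noise scale, demand the peak stand
  # clear of the map's own fluctuations
  if (length(msm) >= 24 && global_max < mean(msm) + 4 * sd(msm))
    stop("untuned site")
  peak_per_level <- apply(msm, 2, max)
  crit <- criterion_frac * global_max
  thr_idx <- which(peak_per_level >= crit)[1]
  if (is.na(thr_idx)) stop("untuned site")
  target_level <- frm$levels_db_spl[thr_idx] + step_db
  li <- match(target_level, frm$levels_db_spl)
  if (is.na(li))
    stop(sprintf("no level at threshold + %g dB (%g dB SPL) in the map",
                 step_db, target_level))
  r <- frm$driven_rate[, li]
  r[is.na(r)] <- 0
  w <- pmax(r - weight_floor_frac * max(r), 0)
  if (sum(w) <= 0) stop("untuned site")
  if (log2_centroid) {
    2^(sum(w * log2(frm$freqs_hz)) / sum(w))
  } else {
    sum(w * frm$freqs_hz) / sum(w)
  }
}
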