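# Synthetic study conditions: vocalization-like stimuli mimicking the three
# guinea-pig call archetypes, and simulated ICC multi-unit responses as
# inhomogeneous Poisson processes whose rate tracks a delayed, scaled,
# optionally compressed copy of the channel envelope. Every generator is a
# pure function of (parameters, seed); the global RNG stream is untouched.

#' Specification of a simulated ICC unit
#'
#' @param kind `"follower"` (rate tracks the delayed envelope),
#'   `"onset_only"` (transient burst at call onset) or `"scrambled"`
#'   (follower formula on a seeded permutation of the envelope bins,
#'   preserving the marginal rate distribution while destroying temporal
#'   locking).
#' @param gain driven rate, spikes/s per unit of normalized envelope.
#' @param delay_ms conduction delay, ms; followers are plausible in 5-20 ms.
#' @param exponent power law applied to the envelope (>= 0; 1 = linear).
#' @param spont_rate spontaneous rate, spikes/s (>= 0).
#' @return A `unit_spec` object.
#' @export
unit_spec <- function(kind = c("follower", "onset_only", "scrambled"),
                      gain = 80, delay_ms = 10, exponent = 1,
                      spont_rate = 8) {
  kind <- match.arg(kind)
  if (gain < 0 || spont_rate < 0) stop("rates must be non-negative")
  if (exponent < 0) stop("exponent must be non-negative")
  if (kind == "follower" && (delay_ms < 0 || delay_ms > 30))
    stop("follower delay_ms must lie in [0, 30]")
  structure(list(kind = kind, gain = gain, delay_ms = delay_ms,
                 exponent = exponent, spont_rate = spont_rate),
            class = "unit_spec")
}

# harmonic stack with time-varying f0 and per-sample amplitude
harmonic_stack <- function(t, f0_of_t, n_harmonics, rolloff = 0.7) {
  dt <- t[2] - t[1]
  phase0 <- 2 * pi * cumsum(f0_of_t) * dt
  x <- 0
  for (h in seq_len(n_harmonics)) x <- x + rolloff^(h - 1) * sin(h * phase0)
  x
}

#' Synthesize a call-like stimulus
#'
#' Three archetypes covering distinct spectrotemporal structure:
#' * `"TSV"` - temporally and spectrally varying: a harmonic stack (6
#'   harmonics) whose fundamental sweeps upward 400 to 1200 Hz, with slow
#'   sinusoidal amplitude modulation.
#' * `"BH"` - broadband with harmonics: a broadband noise burst, a steady
#'   harmonic segment, then a second noise burst.
#' * `"BT"` - broadband transient: a train of short broadband bursts.
#'
#' The raw waveform is passed through [prepare_vocalization()] (bandpass,
#' 25-ms ramps, 50-ms pads), so the result is 100 ms longer than
#' `duration_ms`. Bit-identical for equal seeds.
#'
#' @param kind `"TSV"`, `"BH"` or `"BT"`.
#' @param duration_ms call duration before padding, ms (>= 300; default 500).
#' @param rate_hz sampling rate (default 97500, the rate vocalizations were
#'   digitized at).
#' @param seed RNG seed.
#' @param n_bursts number of bursts for `"BT"` (default 8).
#' @param burst_ms burst duration for `"BT"`, ms (default 20).
#' @param f0_range_hz fundamental sweep range for `"TSV"`.
#' @param am_rate_hz amplitude-modulation rate for `"TSV"`, Hz.
#' @return An [acoustic_stimulus()] labelled with `kind`.
#' @export
synth_call <- function(kind = c("TSV", "BH", "BT"), duration_ms = 500,
                       rate_hz = 97500, seed = 1, n_bursts = 8,
                       burst_ms = 20, f0_range_hz = c(400, 1200),
                       am_rate_hz = 6) {
  kind <- match.arg(kind)
  if (duration_ms < 300) stop("duration_ms must be at least 300")
  n <- round(duration_ms / 1000 * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  x <- with_seed(seed, {
    if (kind == "TSV") {
      f0 <- f0_range_hz[1] +
        (f0_range_hz[2] - f0_range_hz[1]) * seq(0, 1, length.out = n)
      am <- 1 + 0.8 * sin(2 * pi * am_rate_hz * t)
      0.5 * am * harmonic_stack(t, f0, 6L)
    } else if (kind == "BH") {
      seg <- round(n * c(0.3, 0.4, 0.3))
      noise1 <- rnorm(seg[1])
      harm <- harmonic_stack((seq_len(seg[2]) - 1) / rate_hz,
                             rep(600, seg[2]), 6L)
      noise2 <- rnorm(n - seg[1] - seg[2])
      ramp <- function(v) apply_cosine_ramps(v, rate_hz, ramp_ms = 5)
      c(ramp(noise1), ramp(harm), ramp(noise2))
    } else {
      burst_n <- round(burst_ms / 1000 * rate_hz)
      period <- floor(n / n_bursts)
      if (burst_n >= period) stop("bursts overlap; shorten burst_ms or reduce n_bursts")
      x <- numeric(n)
      for (k in seq_len(n_bursts)) {
        i0 <- (k - 1) * period + round((period - burst_n) / 2)
        b <- apply_cosine_ramps(rnorm(burst_n), rate_hz, ramp_ms = 5)
        x[i0 + seq_len(burst_n)] <- b
      }
      x
    }
  })
  prepare_vocalization(x, rate_hz, label = kind)
}

#' Simulate spike trains driven by an envelope
#'
#' Inhomogeneous Poisson counts per 1-ms bin. Followers fire at
#' `spont_rate + gain * env(t - delay_ms)^exponent`; onset-only units add a
#' 30-ms burst at call onset; scrambled controls apply the follower formula
#' to a seeded permutation of the envelope bins. A matched spontaneous set
#' (homogeneous Poisson at `spont_rate`) is always produced. Spike times are
#' placed uniformly within their bin. Deterministic given the seed.
#'
#' @param env a normalized [envelope_trace()].
#' @param unit a [unit_spec()].
#' @param n_trials driven (and spontaneous) trial count (default 20).
#' @param seed RNG seed.
#' @param site_id site identifier carried on the outputs.
#' @return List with [spike_train_set()]s `driven` and `spont`.
#' @export
synth_spike_trains <- function(env, unit, n_trials = 20, seed = 1,
                               site_id = "synthetic") {
  stopifnot(inherits(env, "envelope_trace"), inherits(unit, "unit_spec"))
  if (!env$normalized) stop("env must be max-normalized")
  if (n_trials < 1L) stop("n_trials must be at least 1")
  n_bins <- length(env$values)
  with_seed(seed, {
    e <- env$values
    if (unit$kind == "scrambled") e <- e[sample.int(n_bins)]
    d <- round(unit$delay_ms)
    e_del <- c(numeric(d), e)[seq_len(n_bins)]
    rate <- switch(unit$kind,
      follower  = unit$spont_rate + unit$gain * e_del^unit$exponent,
      scrambled = unit$spont_rate + unit$gain * e_del^unit$exponent,
      onset_only = {
        onset <- which(env$values > 0.1)[1]
        r <- rep(unit$spont_rate, n_bins)
        if (!is.na(onset)) {
          idx <- onset + round(unit$delay_ms) + 0:29
          idx <- idx[idx <= n_bins]
          r[idx] <- r[idx] + unit$gain
        }
        r
      })
    if (max(rate) * 0.001 > 1)
      warning("expected count exceeds 1 spike/bin/trial; Poisson-in-bin approximation degrades")
    draw_set <- function(rates_per_bin, cond) {
      trials <- lapply(seq_len(n_trials), function(i) {
        counts <- rpois(n_bins, rates_per_bin * 0.001)
        hit <- which(counts > 0)
        if (length(hit) == 0L) return(numeric(0))
        sort(rep(hit - 1, counts[hit]) + runif(sum(counts[hit])))
      })
      spike_train_set(site_id, cond, trials)
    }
    list(driven = draw_set(rate, unit$kind),
         spont = draw_set(rep(unit$spont_rate, n_bins), "spontaneous"))
  })
}

#' Synthesize a raw extracellular trace from known spike times
#'
#' Seeded Gaussian noise plus a spike template (dominant negative peak, per
#' the detection convention) inserted at each spike time, with amplitude
#' expressed in units of the noise SD. Overlapping templates simply add.
#'
#' @param spike_times_ms ground-truth spike times, ms.
#' @param duration_ms trace duration, ms.
#' @param rate_hz sampling rate (default 24000, the neural recording rate).
#' @param noise_sd noise standard deviation (default 1).
#' @param amp_sd template negative-peak amplitude, in noise-SD units
#'   (default 5).
#' @param template optional custom template (numeric, dominant negative
#'   peak); default is a 1.2-ms biphasic shape.
#' @param seed RNG seed.
#' @return Numeric trace of `duration_ms / 1000 * rate_hz` samples.
#' @export
synth_raw_trace <- function(spike_times_ms, duration_ms, rate_hz = 24000,
                            noise_sd = 1, amp_sd = 5, template = NULL,
                            seed = 1) {
  n <- round(duration_ms / 1000 * rate_hz)
  if (is.null(template)) {
    tt <- seq(0, 1.2e-3, by = 1 / rate_hz)
    template <- -exp(-((tt - 3e-4) / 1.2e-4)^2) +
      0.35 * exp(-((tt - 7e-4) / 2.2e-4)^2)
  }
  if (min(template) >= 0 || abs(min(template)) <= max(template))
    stop("template must have a dominant negative peak")
  template <- template / abs(min(template))
  with_seed(seed, {
    x <- rnorm(n, sd = noise_sd)
    trough_off <- which.min(template) - 1L
    for (tm in spike_times_ms) {
      i0 <- round(tm / 1000 * rate_hz) + 1L - trough_off
      idx <- i0 + seq_along(template) - 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + amp_sd * noise_sd * template[ok]
    }
    x
  })
}

#' Default pure-tone grid for frequency response maps
#'
#' 500 Hz to 50 kHz in six steps per octave.
#'
#' @return Numeric vector of tone frequencies, Hz.
#' @export
frm_tone_grid <- function() {
  k <- 0:floor(6 * log2(50000 / 500))
  500 * 2^(k / 6)
}

#' Synthesize tone responses for one tuned site
#'
#' Poisson responses on the standard tone grid with Gaussian tuning in log2
#' frequency around `bf_true`; driven rate grows with level above
#' `threshold_level`. Driven spikes fall uniformly in the 5-65 ms window;
#' spontaneous activity is homogeneous over each 200-ms sweep.
#'
#' @param bf_true true best frequency, Hz.
#' @param tuning_width_oct Gaussian SD of the tuning curve, octaves
#'   (default 0.5).
#' @param max_rate driven rate at BF at the highest level, spikes/s
#'   (default 100).
#' @param threshold_level lowest responsive level, dB SPL (default 20).
#' @param spont_rate spontaneous rate, spikes/s (default 5).
#' @param levels_db levels, dB SPL (default 0-70 by 10, the tone levels used
#'   for mapping).
#' @param n_trials trials per (freq, level) (default 4).
#' @param seed RNG seed.
#' @return List: `tone_sets` (list of [spike_train_set()] with
#'   `"<freq>@<level>"` conditions), `spont` ([spike_train_set()]), and
#'   `bf_true`.
#' @export
synth_frm_site <- function(bf_true, tuning_width_oct = 0.5, max_rate = 100,
                           threshold_level = 20, spont_rate = 5,
                           levels_db = seq(0, 70, by = 10), n_trials = 4,
                           seed = 1) {
  freqs <- frm_tone_grid()
  if (bf_true < min(freqs) || bf_true > max(freqs))
    stop("bf_true outside the tone grid")
  win <- c(5, 65); sweep_ms <- 200
  with_seed(seed, {
    tone_sets <- list()
    for (f in freqs) for (L in levels_db) {
      tune <- exp(-log2(f / bf_true)^2 / (2 * tuning_width_oct^2))
      lev <- if (L < threshold_level) 0 else
        (L - threshold_level + 10) / (max(levels_db) - threshold_level + 10)
      rate <- max_rate * tune * lev
      trials <- lapply(seq_len(n_trials), function(i) {
        n_drv <- rpois(1, rate * diff(win) / 1000)
        n_sp <- rpois(1, spont_rate * sweep_ms / 1000)
        sort(c(runif(n_drv, win[1], win[2]), runif(n_sp, 0, sweep_ms)))
      })
      tone_sets[[sprintf("%g@%g", f, L)]] <-
        spike_train_set("synthetic", sprintf("%g@%g", f, L), trials)
    }
    spont <- spike_train_set("synthetic", "spontaneous",
      lapply(seq_len(20), function(i)
        sort(runif(rpois(1, spont_rate * sweep_ms / 1000), 0, sweep_ms))))
    list(tone_sets = tone_sets, spont = spont, bf_true = bf_true)
  })
}
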