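# Lightweight constructors for tests: wrap plain numeric vectors as the
# package's PSTH / envelope containers without running the full chain.

as_psth <- function(bins, site_id = "s1", bf_hz = NA_real_, n_trials = 1L) {
  structure(list(site_id = site_id, bf_hz = bf_hz, bins = as.numeric(bins),
                 t0_ms = 0, n_trials = n_trials, normalized = FALSE),
            class = "psth")
}

as_env <- function(values, bf_hz = 1000, normalized = FALSE) {
  envelope_trace(bf_hz, values, t0_ms = 0, normalized = normalized)
}

# short raised-cosine ramps so test tones start and stop without clicks
apply_ramps_for_test <- function(x, fs, ramp_ms = 5) {
  n <- round(ramp_ms / 1000 * fs)
  r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n)))
  x[seq_len(n)] <- x[seq_len(n)] * r
  idx <- (length(x) - n + 1):length(x)
  x[idx] <- x[idx] * rev(r)
  x
}

# one row of a correlation-results table
result_row <- function(site_id, call, level, r, variant = "full",
                       valid = TRUE, bf = 4000) {
  data.frame(site_id = site_id, call = call, level_db_spl = level,
             model_variant = variant, bf_hz = bf, r_peak = r,
             lag_ms = 10, in_window = TRUE, valid = valid,
             stringsAsFactors = FALSE)
}
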