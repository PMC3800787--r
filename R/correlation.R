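# Lag-windowed peak cross-correlation of driven PSTHs against frequency-
# specific stimulus envelopes, the validity filter, and the summary analyses
# (medians, high-follower fractions, cross-call overlap, cross-level
# consistency, linear-vs-full distribution comparison).
#
# "Cross-correlation" is lag-resolved Pearson correlation: both inputs are
# max-normalized, and a value of 1 must mean a perfect match up to affine
# scaling, which pins down the Pearson normalization.

#' Low-activity validity filter
#'
#' A driven PSTH is a valid case only if more than `min_bins` bins inside the
#' stimulation period exceed four times the SD of the spontaneous-trial PSTH.
#' Exactly `min_bins` suprathreshold bins is excluded.
#'
#' @param psth a `psth` of driven activity (unnormalized counts).
#' @param spont_psth a `psth` built from spontaneous trials only (no
#'   subtraction), on the same 1-ms grid.
#' @param stim_window `c(start_ms, end_ms)` of the stimulation period; the
#'   default `NULL` uses the full PSTH extent.
#' @param sd_multiplier threshold multiplier (default 4).
#' @param min_bins bins that must be exceeded (default 20).
#' @return Logical: does the PSTH pass the activity filter?
#' @export
validity_filter <- function(psth, spont_psth, stim_window = NULL,
                            sd_multiplier = 4, min_bins = 20) {
  stopifnot(inherits(psth, "psth"), inherits(spont_psth, "psth"))
  spont_sd <- sd(spont_psth$bins)
  bins <- psth$bins
  if (!is.null(stim_window)) {
    idx <- seq_along(bins) - 1 + psth$t0_ms
    bins <- bins[idx >= stim_window[1] & idx < stim_window[2]]
  }
  if (spont_sd == 0) {
    if (any(bins != 0)) {
      warning("degenerate spontaneous PSTH (SD = 0); accepting active PSTH")
      return(TRUE)
    }
    return(FALSE)
  }
  sum(bins > sd_multiplier * spont_sd) > min_bins
}

#' Peak cross-correlation between a PSTH and an envelope trace
#'
#' For each integer lag (1-ms grid) the Pearson correlation between the
#' envelope and the PSTH delayed by that lag is computed over the overlapping
#' bins. The reported peak is the maximum inside the acceptance window
#' (default 5-20 ms, the physiological range of acoustic ICC latencies); the
#' `in_window` flag records whether the global peak over the full search
#' range also fell inside that window. Ties break toward the smaller lag.
#'
#' @param psth a `psth` (typically smoothed + normalized; Pearson correlation
#'   is affine-invariant so normalization does not change R).
#' @param env an [envelope_trace()].
#' @param lag_search_ms searched lag range, ms (default `c(0, 30)`).
#' @param accept_window_ms acceptance window, ms (default `c(5, 20)`).
#' @param site_id,call,level_db_spl,model_variant metadata carried through.
#' @param valid validity flag carried through (see [validity_filter()]).
#' @return A `correlation_result`: one-row data frame with `site_id, call,
#'   level_db_spl, model_variant, bf_hz, r_peak, lag_ms, in_window, valid`.
#' @export
peak_correlation <- function(psth, env, lag_search_ms = c(0, 30),
                             accept_window_ms = c(5, 20),
                             site_id = psth$site_id, call = "",
                             level_db_spl = NA_real_, model_variant = "full",
                             valid = TRUE) {
  stopifnot(inherits(psth, "psth"), inherits(env, "envelope_trace"))
  p <- psth$bins
  e <- env$values
  if (length(p) < 100L || length(e) < 100L)
    stop("need at least 100 bins in both series")
  lags <- seq(lag_search_ms[1], lag_search_ms[2])
  n <- min(length(p), length(e))
  if (n - max(lags) < 50L) stop("need at least 50 overlapping bins at every lag")
  r <- vapply(lags, function(l) {
    t_idx <- seq_len(n - l)
    ee <- e[t_idx]
    pp <- p[t_idx + l]
    if (sd(ee) == 0 || sd(pp) == 0)
      stop("zero variance over the overlap at lag ", l, " ms")
    cor(ee, pp)
  }, numeric(1))
  in_acc <- lags >= accept_window_ms[1] & lags <= accept_window_ms[2]
  best_acc <- which(in_acc)[which.max(r[in_acc])]   # which.max -> smallest lag on tie
  best_glob <- which.max(r)
  res <- data.frame(
    site_id = as.character(site_id), call = call,
    level_db_spl = level_db_spl, model_variant = model_variant,
    bf_hz = if (is.null(psth$bf_hz)) NA_real_ else psth$bf_hz,
    r_peak = r[best_acc], lag_ms = lags[best_acc],
    in_window = in_acc[best_glob], valid = valid,
    stringsAsFactors = FALSE)
  class(res) <- c("correlation_result", "data.frame")
  res
}

as_result_table <- function(results) {
  if (is.data.frame(results)) return(results)
  do.call(rbind, results)
}

#' Summarize peak-correlation results
#'
#' Per (call, level, model variant): number of valid cases, median R,
#' fraction of cases at or above the high-follower threshold, and the BF
#' range covered.
#'
#' @param results a data frame of correlation results (rows as produced by
#'   [peak_correlation()]), or a list of them.
#' @param high_threshold high-follower criterion, applied as R >=
#'   `high_threshold` (default 0.85).
#' @param valid_only keep only rows with `valid == TRUE` (default TRUE).
#' @return Data frame with columns `call, level_db_spl, model_variant, n,
#'   median_r, frac_high, bf_min_hz, bf_max_hz`.
#' @export
summarize_correlations <- function(results, high_threshold = 0.85,
                                   valid_only = TRUE) {
  d <- as_result_table(results)
  if (valid_only) d <- d[d$valid, , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid correlation results to summarize")
  key <- interaction(d$call, d$level_db_spl, d$model_variant, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(call = g$call[1], level_db_spl = g$level_db_spl[1],
               model_variant = g$model_variant[1], n = nrow(g),
               median_r = median(g$r_peak),
               frac_high = mean(g$r_peak >= high_threshold),
               bf_min_hz = suppressWarnings(min(g$bf_hz, na.rm = TRUE)),
               bf_max_hz = suppressWarnings(max(g$bf_hz, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$call, out$level_db_spl, out$model_variant), , drop = FALSE]
}

#' Cross-call overlap of high-follower sites
#'
#' For each call: among sites high (R >= threshold) on that call, the
#' fraction also high on every other call, the fraction high on at least one
#' other call, and pairwise fractions. A site missing on another call counts
#' as not high there.
#'
#' @param results correlation results (one row per site x call; pass a single
#'   level and model variant).
#' @param threshold high-follower criterion (default 0.85).
#' @return List with data frames `per_call` (`call, n_high, frac_all_others,
#'   frac_at_least_one`) and `pairwise` (`call_a, call_b, frac`).
#' @export
cross_call_overlap <- function(results, threshold = 0.85) {
  d <- as_result_table(results)
  d <- d[d$valid, , drop = FALSE]
  calls <- sort(unique(d$call))
  if (length(calls) < 2L) stop("need results for at least two calls")
  sites <- unique(d$site_id)
  seen <- table(d$site_id)
  if (!any(seen >= 2L)) stop("no site present in at least two calls")
  high <- matrix(FALSE, length(sites), length(calls),
                 dimnames = list(sites, calls))
  for (i in seq_len(nrow(d)))
    high[d$site_id[i], d$call[i]] <- d$r_peak[i] >= threshold
  per_call <- do.call(rbind, lapply(calls, function(a) {
    others <- setdiff(calls, a)
    idx <- which(high[, a])
    if (length(idx) == 0L)
      return(data.frame(call = a, n_high = 0L, frac_all_others = NA_real_,
                        frac_at_least_one = NA_real_))
    oth <- high[idx, others, drop = FALSE]
    data.frame(call = a, n_high = length(idx),
               frac_all_others = mean(apply(oth, 1, all)),
               frac_at_least_one = mean(apply(oth, 1, any)),
               stringsAsFactors = FALSE)
  }))
  pairs <- expand.grid(call_a = calls, call_b = calls,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$call_a != pairs$call_b, , drop = FALSE]
  pairs$frac <- mapply(function(a, b) {
    idx <- which(high[, a])
    if (length(idx) == 0L) NA_real_ else mean(high[idx, b])
  }, pairs$call_a, pairs$call_b)
  rownames(pairs) <- NULL
  list(per_call = per_call, pairwise = pairs)
}

#' Cross-level consistency of high-follower sites
#'
#' Among sites with data at every requested level, the fraction whose R
#' reaches the threshold at all of them.
#'
#' @param results correlation results for one call and model variant across
#'   levels.
#' @param levels_db_spl levels that must all be present (default
#'   `c(40, 50, 60)`).
#' @param threshold high-follower criterion (default 0.85).
#' @return List: `fraction`, `n_consistent`, `n_with_all_levels`.
#' @export
cross_level_consistency <- function(results, levels_db_spl = c(40, 50, 60),
                                    threshold = 0.85) {
  d <- as_result_table(results)
  d <- d[d$valid & d$level_db_spl %in% levels_db_spl, , drop = FALSE]
  by_site <- split(d, d$site_id)
  complete <- Filter(function(g)
    all(levels_db_spl %in% g$level_db_spl), by_site)
  if (length(complete) == 0L)
    stop("no site has data at all requested levels")
  ok <- vapply(complete, function(g) {
    all(vapply(levels_db_spl, function(L)
      any(g$r_peak[g$level_db_spl == L] >= threshold), logical(1)))
  }, logical(1))
  list(fraction = mean(ok), n_consistent = sum(ok),
       n_with_all_levels = length(ok))
}

#' Compare two correlation-value distributions (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, as used to compare
#' linear-path against full-model correlation values: exact enumeration for
#' small tie-free samples (both n <= 20), normal approximation with
#' continuity and tie correction otherwise. Two identical constant samples
#' return p = 1 with a warning.
#'
#' @param r_linear,r_full numeric vectors (each length >= 3).
#' @return List with `statistic` (rank-sum W), `p_value`, `method`.
#' @export
compare_distributions <- function(r_linear, r_full) {
  x <- as.numeric(r_linear); y <- as.numeric(r_full)
  if (length(x) < 3L || length(y) < 3L) stop("need at least 3 values per group")
  if (length(unique(c(x, y))) == 1L) {
    warning("both samples are a single constant; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all values tied)"))
  }
  use_exact <- length(x) <= 20L && length(y) <= 20L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}
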