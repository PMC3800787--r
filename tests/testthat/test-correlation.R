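# Peak cross-correlation, validity filtering and the summary analyses.

make_env_series <- function(n = 600, seed = 3) {
  set.seed(seed)
  v <- smooth_10ms(abs(cumsum(rnorm(n))))
  normalize_max(v - min(v) + 0.01)
}

test_that("validity filter counts suprathreshold bins against 4 x spont SD", {
  set.seed(2)
  spont <- as_psth(rpois(600, 3))
  thr <- 4 * sd(spont$bins)
  base <- rep(0, 600)
  expect_false(validity_filter(as_psth(base), spont))
  # exactly 20 bins above threshold: excluded; 21: included
  v20 <- base; v20[seq(40, 420, by = 20)] <- thr + 1
  expect_length(which(v20 > thr), 20L)
  expect_false(validity_filter(as_psth(v20), spont))
  v21 <- v20; v21[450] <- thr + 1
  expect_true(validity_filter(as_psth(v21), spont))
  # the stimulation window restricts which bins count
  expect_false(validity_filter(as_psth(v21), spont, stim_window = c(0, 30)))
  # degenerate spontaneous activity: accept with a warning
  expect_warning(ok <- validity_filter(as_psth(v21), as_psth(rep(0, 600))),
                 "degenerate")
  expect_true(ok)
  expect_false(validity_filter(as_psth(base), as_psth(rep(0, 600))))
})

test_that("peak correlation finds exact and affine-shifted copies", {
  e <- make_env_series()
  env <- as_env(e, normalized = TRUE)
  delayed <- function(d) c(rep(e[1], d), e)[seq_along(e)]
  r10 <- peak_correlation(as_psth(delayed(10)), env)
  expect_equal(r10$r_peak, 1.0, tolerance = 1e-12)
  expect_equal(r10$lag_ms, 10)
  expect_true(r10$in_window)
  # Pearson correlation is affine-invariant
  r7 <- peak_correlation(as_psth(2 * delayed(7) + 3), env)
  expect_equal(r7$r_peak, 1.0, tolerance = 1e-12)
  expect_equal(r7$lag_ms, 7)
  # normalization of either series does not change R
  r7n <- peak_correlation(as_psth(normalize_max(delayed(7))), env)
  expect_equal(r7n$r_peak, r7$r_peak, tolerance = 1e-12)
})

test_that("a global peak outside 5-20 ms clears the in_window flag", {
  e <- make_env_series()
  env <- as_env(e, normalized = TRUE)
  d2 <- c(rep(e[1], 2), e)[seq_along(e)]
  res <- peak_correlation(as_psth(d2), env)
  expect_false(res$in_window)
  expect_gte(res$lag_ms, 5)  # reported peak still from the window
})

test_that("lag ties break toward the smaller lag", {
  # period-5 series: equal peaks at lags 5, 10, 15, 20
  k <- 0:599
  e <- 1.5 + sin(2 * pi * k / 5)
  res <- peak_correlation(as_psth(e), as_env(e))
  expect_equal(res$lag_ms, 5)
})

test_that("noisy delayed copy attenuates R by 1/sqrt(1 + noise/signal)", {
  e <- make_env_series(n = 800)
  env <- as_env(e, normalized = TRUE)
  sig_sd <- sd(e)
  set.seed(42)
  r <- replicate(20, {
    psth <- c(rep(0, 10), e)[seq_along(e)] + rnorm(length(e), sd = sig_sd)
    peak_correlation(as_psth(psth), env)$r_peak
  })
  expect_equal(mean(r), 1 / sqrt(2), tolerance = 0.05)
})

test_that("peak correlation validates its inputs", {
  e <- make_env_series()
  expect_error(peak_correlation(as_psth(e[1:60]), as_env(e[1:60])), "100 bins")
  expect_error(peak_correlation(as_psth(rep(1, 600)), as_env(e)),
               "zero variance")
})

test_that("summaries report n, median and high-follower fraction", {
  d <- rbind(result_row("s1", "BT", 60, 0.9), result_row("s2", "BT", 60, 0.8),
             result_row("s3", "BT", 60, 0.86))
  s <- summarize_correlations(d)
  expect_equal(s$n, 3L)
  expect_equal(s$median_r, 0.86)
  expect_equal(s$frac_high, 2 / 3)
  # single result
  s1 <- summarize_correlations(result_row("s1", "TSV", 60, 0.5))
  expect_equal(s1$median_r, 0.5)
  expect_equal(s1$frac_high, 0)
  # the 0.85 criterion is inclusive
  expect_equal(summarize_correlations(result_row("s", "BT", 60, 0.85))$frac_high, 1)
  expect_error(summarize_correlations(result_row("s", "BT", 60, 0.9,
                                                 valid = FALSE)), "no valid")
})

test_that("cross-call overlap matches hand enumeration", {
  d <- rbind(
    result_row("s1", "A", 60, 0.9), result_row("s2", "A", 60, 0.9),
    result_row("s1", "B", 60, 0.9), result_row("s2", "B", 60, 0.1),
    result_row("s1", "C", 60, 0.9), result_row("s2", "C", 60, 0.1))
  ov <- cross_call_overlap(d)
  a <- ov$per_call[ov$per_call$call == "A", ]
  expect_equal(a$n_high, 2L)
  expect_equal(a$frac_all_others, 0.5)
  expect_equal(a$frac_at_least_one, 0.5)
  ab <- ov$pairwise[ov$pairwise$call_a == "A" & ov$pairwise$call_b == "B", ]
  expect_equal(ab$frac, 0.5)
  # everyone high everywhere: all fractions 1
  d2 <- d; d2$r_peak <- 0.95
  ov2 <- cross_call_overlap(d2)
  expect_true(all(ov2$per_call$frac_all_others == 1))
  expect_true(all(ov2$pairwise$frac == 1))
  expect_error(cross_call_overlap(d[1:2, ]), "two calls")
})

test_that("cross-level consistency requires the threshold at every level", {
  d <- rbind(result_row("s1", "BT", 40, 0.9), result_row("s1", "BT", 50, 0.9),
             result_row("s1", "BT", 60, 0.9))
  expect_equal(cross_level_consistency(d)$fraction, 1)
  d$r_peak[2] <- 0.84  # one level just below the criterion
  cc <- cross_level_consistency(d)
  expect_equal(cc$fraction, 0)
  expect_equal(cc$n_with_all_levels, 1L)
  # sites missing a level drop from the denominator
  d2 <- rbind(d, result_row("s2", "BT", 40, 0.99))
  expect_equal(cross_level_consistency(d2)$n_with_all_levels, 1L)
  expect_error(cross_level_consistency(d[1:2, ]), "all requested levels")
})

test_that("rank-sum comparison handles exact, approximate and degenerate cases", {
  # most extreme arrangement of 3 vs 3: exact two-sided p = 2/20
  expect_equal(compare_distributions(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # identical samples: no evidence of a shift
  same <- c(0.5, 0.6, 0.7, 0.8)
  expect_gt(compare_distributions(same, same)$p_value, 0.9)
  # identical constants: p = 1 with a warning
  expect_warning(res <- compare_distributions(rep(0.9, 5), rep(0.9, 6)),
                 "constant")
  expect_equal(res$p_value, 1)
  expect_error(compare_distributions(c(1, 2), c(1, 2, 3)), "at least 3")
  # large samples take the normal-approximation path
  set.seed(9)
  res <- compare_distributions(rnorm(40), rnorm(40) + 2)
  expect_equal(res$method, "normal approximation")
  expect_lt(res$p_value, 1e-6)
})
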