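# Spike detection, driven PSTHs, frequency response maps, BF estimation.

test_that("detect_spikes finds inserted troughs and ignores positive peaks", {
  fs <- 24000
  noise <- synth_raw_trace(numeric(0), 500, fs, seed = 1)
  sdn <- sd(noise)
  # one biphasic spike with a -5 SD trough
  tr <- synth_raw_trace(200, 500, fs, noise_sd = sdn, amp_sd = 5, seed = 1)
  det <- detect_spikes(tr, fs, noise_sd = sdn)
  hits <- det[abs(det - 200) <= 0.5]
  expect_length(hits, 1L)
  # a +6 SD positive-only deflection is not a spike
  tr2 <- noise
  i0 <- 4800 + 0:23
  tr2[i0] <- tr2[i0] + 6 * sdn * sin(pi * (0:23) / 23)
  det_noise <- detect_spikes(noise, fs, noise_sd = sdn)
  det_pos <- detect_spikes(tr2, fs, noise_sd = sdn)
  win <- function(d) d[d >= 195 & d <= 205]
  expect_equal(win(det_pos), win(det_noise))
  expect_error(detect_spikes(c(rnorm(1000), NA), fs), "finite")
})

test_that("detection count is monotone non-increasing in the threshold", {
  tr <- synth_raw_trace(seq(20, 480, by = 20), 500, 24000, amp_sd = 4,
                        seed = 7)
  counts <- vapply(c(2.5, 3.5, 4.5, 6), function(th)
    length(detect_spikes(tr, 24000, threshold_sd = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("build_psth bins and subtracts spontaneous activity", {
  # one spike at 12.4 ms, no spontaneous: bin 12 gets the single count
  drv <- spike_train_set("s1", "stim", list(12.4))
  p <- build_psth(drv, NULL, 20)
  expect_equal(p$bins, c(rep(0, 12), 1, rep(0, 7)))
  # empty spontaneous trials: PSTH stays the raw driven totals
  sp0 <- spike_train_set("s1", "spontaneous", list(numeric(0), numeric(0)))
  expect_equal(build_psth(drv, sp0, 20)$bins, p$bins)
  # statistically identical driven and spontaneous Poisson activity: the
  # driven PSTH mean is zero within 3 SE (Poisson oracle)
  n_tr <- 20; dur <- 1000; rate <- 30
  mk <- function(seed, cond) {
    set.seed(seed)
    spike_train_set("s1", cond, lapply(1:n_tr, function(i)
      sort(runif(rpois(1, rate * dur / 1000), 0, dur))))
  }
  psth <- build_psth(mk(1, "stim"), mk(2, "spontaneous"), dur)
  # per-bin variance ~ 2 * n_tr * rate/1000; SE of the grand mean over dur bins
  se <- sqrt(2 * n_tr * rate / 1000 / dur)
  expect_lt(abs(mean(psth$bins)), 3 * se)
})

test_that("build_psth is additive over disjoint trial subsets", {
  set.seed(5)
  trials <- lapply(1:10, function(i) sort(runif(rpois(1, 40), 0, 500)))
  all_tr <- spike_train_set("s", "c", trials)
  first <- spike_train_set("s", "c", trials[1:4])
  rest <- spike_train_set("s", "c", trials[5:10])
  expect_equal(build_psth(all_tr, NULL, 500)$bins,
               build_psth(first, NULL, 500)$bins +
                 build_psth(rest, NULL, 500)$bins)
})

test_that("compute_frm applies the driven-rate arithmetic", {
  mk <- function(cond, times_per_trial) spike_train_set("s", cond,
    times_per_trial)
  # 12 spikes in the 5-65 ms window over 4 trials, no spont: 50 spikes/s
  sets <- list(
    mk("1000@40", list(c(10, 20, 30), c(15, 25, 35), c(12, 22, 32),
                       c(40, 50, 60))),
    mk("1000@50", list(numeric(0), numeric(0), numeric(0), numeric(0))),
    mk("2000@40", list(numeric(0), numeric(0), numeric(0), numeric(0))),
    mk("2000@50", list(numeric(0), numeric(0), numeric(0), numeric(0))))
  frm <- compute_frm(sets, spont = NULL)
  expect_equal(frm$driven_rate["1000", "40"], 12 / (4 * 0.06))
  expect_equal(frm$driven_rate["1000", "50"], 0)
  # spikes outside 5-65 ms do not count
  sets2 <- sets
  sets2[[2]] <- mk("1000@50", list(c(1, 70, 100), numeric(0), numeric(0),
                                   numeric(0)))
  expect_equal(compute_frm(sets2, NULL)$driven_rate["1000", "50"], 0)
  expect_error(compute_frm(sets[1:2], NULL), "2 frequencies")
})

test_that("FRM CSV round-trips", {
  site <- synth_frm_site(4000, seed = 3)
  frm <- compute_frm(site$tone_sets, site$spont)
  path <- tempfile(fileext = ".csv")
  write_frm_csv(frm, path)
  back <- read_frm_csv(path)
  expect_equal(back$freqs_hz, frm$freqs_hz)
  expect_equal(back$levels_db_spl, frm$levels_db_spl)
  expect_equal(unname(back$driven_rate), unname(frm$driven_rate),
               tolerance = 1e-10)
  unlink(path)
})

test_that("estimate_bf computes the log2-frequency centroid above threshold", {
  mk_frm <- function(rates_at_20db, freqs = c(2000, 4000, 8000)) {
    structure(list(freqs_hz = freqs, levels_db_spl = c(10, 20),
                   driven_rate = cbind(`10` = rates_at_20db * 0.3,
                                       `20` = rates_at_20db)),
              class = "frequency_response_map")
  }
  # single responsive frequency: BF is that frequency exactly
  expect_equal(estimate_bf(mk_frm(c(0, 50, 0))), 4000)
  # symmetric response in log2 f around 4 kHz
  expect_equal(estimate_bf(mk_frm(c(20, 50, 20))), 4000)
  # equal weights at 2 and 8 kHz: geometric (log2) centroid 4 kHz, not 5 kHz
  expect_equal(estimate_bf(mk_frm(c(30, 0, 30))), 4000)
  expect_equal(estimate_bf(mk_frm(c(30, 0, 30)), log2_centroid = FALSE), 5000)
  # scale invariance of the centroid
  f1 <- mk_frm(c(10, 40, 25))
  f2 <- f1; f2$driven_rate <- f2$driven_rate * 7.3
  expect_equal(estimate_bf(f1), estimate_bf(f2))
  # untuned site: nothing crosses the criterion
  expect_error(estimate_bf(mk_frm(c(0, 0, 0))), "untuned")
})

test_that("synthetic tuned site round-trips through FRM to its BF", {
  site <- synth_frm_site(8000, tuning_width_oct = 0.5, seed = 2)
  frm <- compute_frm(site$tone_sets, site$spont)
  bf <- estimate_bf(frm)
  expect_lt(abs(log2(bf / 8000)), 0.25)
})

test_that("spike tables round-trip through CSV", {
  sets <- list(spike_train_set("s1", "TSV@60", list(c(1.5, 7.2), numeric(0))),
               spike_train_set("s1", "spontaneous", list(c(3.3), c(9.9))))
  path <- tempfile(fileext = ".csv")
  write_spike_csv(sets, path)
  back <- read_spike_csv(path)
  expect_length(back, 2L)
  drv <- back[[grep("TSV", names(back))]]
  expect_equal(drv$n_trials, 2L)
  expect_equal(drv$trials[[1]], c(1.5, 7.2))
  expect_equal(drv$trials[[2]], numeric(0))
  unlink(path)
})
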