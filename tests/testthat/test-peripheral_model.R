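# Middle-ear filter and DRNL channel behaviour.

test_that("middle-ear filter matches its designed magnitude response", {
  fs <- 97500
  t <- (0:97499) / fs
  # independent oracle: evaluate the two designed Butterworth transfer
  # functions directly on the unit circle
  nyq <- fs / 2
  b1 <- signal::butter(2, c(4000, 25000) / nyq, type = "pass")
  b2 <- signal::butter(3, c(700, 30000) / nyq, type = "pass")
  resp <- function(flt, f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^(seq_along(flt$b) - 1)) /
          sum(flt$a * z^(seq_along(flt$a) - 1)))
  }
  hmag <- function(f) resp(b1, f) * resp(b2, f)
  tone10k <- acoustic_stimulus(sin(2 * pi * 10000 * t), fs)
  sv <- middle_ear_filter(tone10k)
  amp10 <- max(abs(sv$samples[20000:80000]))
  expect_equal(amp10, 1.4e-10 * hmag(10000), tolerance = 1e-3)
  # 100 Hz sits below both low band edges: at least 40 dB below 10 kHz
  sv100 <- middle_ear_filter(acoustic_stimulus(sin(2 * pi * 100 * t), fs))
  amp100 <- max(abs(sv100$samples[20000:80000]))
  expect_lt(20 * log10(amp100 / amp10), -40)
  # zero in, zero out
  svz <- middle_ear_filter(acoustic_stimulus(numeric(5000), fs))
  expect_equal(svz$samples, numeric(5000))
})

test_that("middle-ear filter clips band edges at low rates with a warning", {
  fs <- 48000
  w <- capture_warnings(middle_ear_filter(acoustic_stimulus(rnorm(4800), fs)))
  # both the 25- and 30-kHz edges exceed Nyquist at this rate
  expect_length(w, 2L)
  expect_match(w, "clipped", all = TRUE)
})

test_that("broken stick is odd, continuous and matches its two branches", {
  p <- list(bs_a = 1, bs_b = 1, bs_nu = 0.25)
  expect_identical(broken_stick(0, p), 0)
  # below the knee the linear branch is active
  expect_equal(broken_stick(1e-8, p), 1e-8)
  # compressive branch with sign preserved: -min(16, 16^0.25) = -2
  expect_equal(broken_stick(-16, p), -2)
  # odd symmetry and monotonicity on a grid
  x <- seq(-20, 20, by = 0.37)
  expect_equal(broken_stick(-x, p), -broken_stick(x, p))
  y <- broken_stick(seq(0, 50, by = 0.01), p)
  expect_true(all(diff(y) >= 0))
  # continuity across the knee (a|x| = b|x|^nu at |x| = 1)
  eps <- 1e-9
  expect_equal(broken_stick(1 - eps, p), broken_stick(1 + eps, p),
               tolerance = 1e-6)
})

test_that("default per-channel parameter laws are stable (regression)", {
  p <- drnl_params(8000, 97500)
  expect_equal(p$lin_gain, 78.34345361, tolerance = 1e-8)
  expect_equal(p$lin_gt_cf_hz, 6796.190415, tolerance = 1e-8)
  expect_equal(p$lin_gt_bw_hz, 2336.886895, tolerance = 1e-8)
  expect_equal(p$nl_gt_bw_hz, 1158.22302, tolerance = 1e-7)
  expect_equal(p$bs_a, 4230.48826, tolerance = 1e-7)
  expect_equal(p$bs_b, 2.318482054e-08, tolerance = 1e-6)
  expect_equal(p$bs_nu, 0.1)
  expect_equal(p$nl_gt_cf_hz, 8000)
  expect_error(drnl_params(60000, 97500), "Nyquist")
})

test_that("DRNL coefficients load from YAML and validate", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("bs_nu: 0.2", "bs_a:", "  p0: 1.5", "  m: 0.5"), path)
  co <- read_drnl_coefs(path)
  expect_equal(co$bs_nu, 0.2)
  expect_equal(unname(co$bs_a), c(1.5, 0.5))
  expect_equal(co$lin_bw, drnl_default_coefs()$lin_bw)  # untouched default
  writeLines("bs_nu: 1.5", path)
  expect_error(read_drnl_coefs(path), "bs_nu")
  writeLines("nonsense: 3", path)
  expect_error(read_drnl_coefs(path), "unknown")
  unlink(path)
})

test_that("gammatone cascade has unit gain at cf and selectivity off cf", {
  fs <- 97500
  t <- (0:48749) / fs
  at_cf <- gammatone_cascade(sin(2 * pi * 8000 * t), 8000, 500, fs, 3)
  expect_equal(max(abs(at_cf[20000:40000])), 1, tolerance = 1e-3)
  off <- gammatone_cascade(sin(2 * pi * 10000 * t), 8000, 500, fs, 3)
  expect_lt(max(abs(off[20000:40000])), 0.1)
})

test_that("linear path is homogeneous; full channel is not at high level", {
  fs <- 97500
  t <- (0:48749) / fs
  x <- 0.02 * sin(2 * pi * 3000 * t)
  p <- drnl_params(3000, fs)
  lin <- function(s) drnl_channel(middle_ear_filter(
    acoustic_stimulus(s, fs)), p, variant = "linear")$samples
  base <- lin(x)
  for (c_ in c(1e-3, 1e3)) {
    scaled <- lin(c_ * x)
    expect_lt(max(abs(scaled - c_ * base)) / max(abs(scaled)), 1e-10)
  }
  # full channel: compression breaks homogeneity for a loud BF tone
  full <- function(s) drnl_channel(middle_ear_filter(
    acoustic_stimulus(s, fs)), p, variant = "full")$samples
  loud <- calibrate_level(acoustic_stimulus(x, fs), 80)$samples
  dev <- max(abs(full(1e3 * loud) - 1e3 * full(loud))) /
    max(abs(full(1e3 * loud)))
  expect_gt(dev, 0.01)
})

test_that("both DRNL paths are time-invariant", {
  fs <- 97500
  n <- 30000
  x <- rnorm(n) * 1e-9
  sv <- function(s) structure(list(samples = s, rate_hz = fs),
                              class = "stapes_velocity")
  p <- drnl_params(4000, fs)
  k <- 137
  shifted <- c(numeric(k), x)[1:n]
  for (v in c("linear", "nonlinear")) {
    y <- drnl_channel(sv(x), p, variant = v)$samples
    y_sh <- drnl_channel(sv(shifted), p, variant = v)$samples
    expect_equal(y_sh[(k + 1):n], y[1:(n - k)], tolerance = 1e-10)
  }
})

test_that("zero input maps to zero output through the whole channel", {
  fs <- 97500
  sv <- middle_ear_filter(acoustic_stimulus(numeric(20000), fs))
  bm <- drnl_channel(sv, drnl_params(8000, fs))
  expect_equal(bm$samples, numeric(20000))
})

test_that("filterbank equals channel-by-channel composition and is independent", {
  fs <- 97500
  t <- (0:33749) / fs
  stim <- calibrate_level(
    acoustic_stimulus(sin(2 * pi * 8000 * t), fs), 60)
  fb <- drnl_filterbank(stim, c(2000, 8000, 16000))
  single <- drnl_channel(middle_ear_filter(stim), drnl_params(8000, fs))
  expect_equal(fb[[2]]$samples, single$samples)
  # an 8-kHz tone drives the 8-kHz channel hardest
  peaks <- vapply(fb, function(b) max(abs(b$samples)), numeric(1))
  expect_equal(which.max(peaks), 2L)
  # permuting the BF list permutes the outputs identically
  fb_perm <- drnl_filterbank(stim, c(16000, 2000, 8000))
  expect_equal(fb_perm[[3]]$samples, fb[[2]]$samples)
  expect_error(drnl_filterbank(stim, numeric(0)), "empty")
})

test_that("BF-tone input/output growth is compressive in the mid-level region", {
  fs <- 97500
  bf <- 8000
  t <- (0:24374) / fs  # 250-ms tone keeps this quick
  tone <- acoustic_stimulus(sin(2 * pi * bf * t), fs)
  p <- drnl_params(bf, fs)
  out_db <- vapply(c(50, 60), function(L) {
    sv <- middle_ear_filter(calibrate_level(tone, L))
    bm <- drnl_channel(sv, p)
    20 * log10(sqrt(mean(bm$samples[10000:20000]^2)))
  }, numeric(1))
  slope <- diff(out_db) / 10
  expect_lt(slope, 1)
})
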