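---
title: "Envelope following in the auditory midbrain: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope following in the auditory midbrain: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envfollow)
```

## The question the package answers

Neurons in the central nucleus of the inferior colliculus (ICC) receive
sound only after the outer/middle ear and the cochlea have filtered,
compressed and decomposed it by frequency. Asking whether an ICC site
"follows the envelope" of a vocalization therefore only makes sense against
the envelope *that site's frequency channel actually received*, not the
broadband waveform. `envfollow` implements that comparison end to end:

1. a guinea-pig peripheral ear model turns calibrated sound pressure into
   basilar-membrane velocity at any best frequency (BF);
2. the Hilbert envelope of that channel, binned at 1 ms, smoothed with a
   10-ms sliding average and max-normalized, is the frequency-specific
   stimulus envelope;
3. driven post-stimulus time histograms (PSTHs) from multi-unit spike data
   are compared to that envelope by lag-windowed peak Pearson correlation,
   and the resulting R values are summarized across calls, levels and sites.

Because the corresponding animal recordings are not publicly deposited, the
package also ships a fully seeded synthetic-data module (call-like stimuli
and envelope-driven Poisson units) so every stage runs against known ground
truth.

## The peripheral ear model

### Middle ear

Sound pressure $p(t)$ (Pa) passes through a cascade of two causal
Butterworth bandpasses — 2nd order, 4–25 kHz, and 3rd order, 700 Hz–30 kHz,
both unity passband gain — and is scaled by $1.4\times10^{-10}$ to give
stapes velocity in m/s. The cascade imposes the middle ear's bandpass tilt:
components below ~700 Hz are strongly attenuated, which is why low-frequency
channels of the cochleagram are weak relative to the stimulus spectrogram.

### The DRNL channel

Each BF channel is a dual-resonance non-linear (DRNL) filter: two parallel
paths applied to stapes velocity and summed.

* **Linear path**: gain $g$ → three first-order gammatone filters (centre
  $CF_{lin}$, bandwidth $BW_{lin}$) → four 2nd-order Butterworth lowpasses
  (cutoff $LP_{lin}$). This path is linear and time-invariant; its output
  scales exactly with the input.
* **Non-linear path**: three gammatones at BF → broken-stick compressor
  $y = \mathrm{sign}(x)\,\min(a|x|,\, b|x|^{\nu})$ → three more gammatones →
  four 1st-order Butterworth lowpasses at BF.

The broken stick is linear ($a|x|$) below the knee and compressive
($b|x|^{\nu}$, $\nu = 0.1$) above it, so a BF tone grows at 1 dB/dB at low
levels, at a fraction of a dB/dB through the mid levels, and re-linearizes
when the linear path overtakes the compressed path at high levels — the
classic basilar-membrane input/output shape. With the shipped parameters the
knee for a BF tone sits near 40 dB SPL.

First-order gammatones are realized as complex one-pole resonators
(impulse response $\propto e^{-2\pi\,bw\,t}\cos(2\pi\,cf\,t)$), each section
normalized to unit gain at its centre frequency; the cascade is implemented
in compiled code (`src/gammatone.cpp`). The Butterworth lowpasses are
applied forward-only (causal), matching a physical cochlea; start-up
transients are absorbed by the 50-ms silent pads on every prepared stimulus.

### Per-channel parameters

All per-BF parameters follow log-linear laws
$\log_{10}(p) = p_0 + m\,\log_{10}(BF)$ and are fully config-driven (YAML,
see `read_drnl_coefs()`); the shipped defaults are:

| parameter | $p_0$ | $m$ | meaning |
|---|---|---|---|
| `lin_cf` | 0.339 | 0.895 | linear-path gammatone centre (Hz) |
| `lin_bw` | 1.30 | 0.53 | linear-path bandwidth (Hz) |
| `lin_lp` | 0.339 | 0.895 | linear-path lowpass cutoff (Hz) |
| `lin_gain` | 5.68 | −0.97 | linear-path gain |
| `nl_cf`, `nl_lp` | 0 | 1 | non-linear path centre/cutoff = BF |
| `nl_bw` | 0.80 | 0.58 | non-linear bandwidth (Hz) |
| `bs_a` | 1.87 | 0.45 | broken-stick linear gain |
| `bs_b` | −11.05 | 0.875 | broken-stick compressive gain (SI) |
| `bs_nu` | 0.1 | — | compression exponent |

One unit conversion deserves a note: the guinea-pig DRNL literature
parametrizes the compressive gain $b$ for stapes velocities derived from
pressure expressed in micropascal. This package works in SI pascal
throughout, so velocities are $10^{6}$ times smaller and the compressive
branch must satisfy $b_{SI} = b\,(10^{-6})^{1-\nu} = b\cdot10^{-5.4}$ for
$\nu = 0.1$; the shipped intercept is therefore $-5.65 - 5.4 = -11.05$.
This keeps the compression knee at its physiological place (~40 dB SPL for
a BF tone) while letting `middle_ear_filter()` take pascal in and put
m/s out. Exact numeric agreement with any particular published channel
implementation is not claimed; the laws are regression-tested and every
coefficient can be overridden from a file.

## From channel output to the frequency-specific envelope

`drnl_output()` composes, in order: Hilbert envelope (magnitude of the FFT
analytic signal), 1-ms binning (within-bin mean — anti-aliasing-friendly and
the same semantics as PSTH binning), a centred 10-bin sliding average with
shrinking edge windows, and division by the maximum.

The 10-ms boxcar passes envelope fluctuations up to roughly 100 Hz — the
upper limit of typical ICC temporal following — and nulls a 100-Hz
modulation exactly (the boxcar spans one full period). A modulation at
frequency $f$ is attenuated by the discrete boxcar factor
$\left|\sin(\pi f n T)\,/\,(n \sin(\pi f T))\right|$ with $n = 10$ bins and
$T = 1$ ms: 0.639 at 50 Hz. Smoothing is applied before normalization;
correlation values are invariant to this order (Pearson correlation is
affine-invariant), so only diagnostic displays could notice.

## Neural side

* **Spike detection**: traces are bandpassed 300–3000 Hz (2nd-order
  Butterworth, zero-phase so spike times are not lag-shifted), the noise SD
  is estimated robustly as $\mathrm{median}(|x|)/0.6745$, and local minima
  below $-3.5\,\mathrm{SD}$ are events, one per 1-ms lockout. Only negative
  troughs count.
* **Driven PSTH**: total driven spikes per 1-ms bin minus the per-bin mean
  spontaneous count scaled to the driven trial count; bins may go negative.
  For correlation the PSTH gets the same 10-ms smoothing and
  max-normalization as the envelope.
* **Validity filter**: a case enters the analysis only if more than 20
  stimulation-period bins exceed 4 × SD of the spontaneous-trial PSTH
  (exactly 20 is excluded). The stimulation period runs from call onset to
  offset + 20 ms, the longest accepted neural lag.
* **Frequency response maps**: driven rate (total minus spontaneous
  expectation) in a 5–65 ms post-onset window over a 500 Hz–50 kHz tone grid
  with six steps per octave.
* **Best frequency**: the rate-weighted centroid in $\log_2$ frequency at
  10 dB above threshold. Threshold is automated as the lowest level whose
  (3-point frequency-smoothed) peak rate reaches 20% of the map maximum; the
  visual threshold it stands in for is not recoverable, so the criterion is
  exposed as a parameter. Centroid weights are floored at 20% of the target
  row's maximum before clipping at zero: off-peak cells of a
  spontaneous-subtracted map carry zero-mean Poisson noise, and summing
  every positive cell across a 6.6-octave grid pulls the centroid toward
  the grid centre (a ~0.15-octave bias in simulation); the proportional
  floor removes that bias while keeping the estimate invariant to overall
  rate scaling. `weight_floor_frac = 0` restores plain clipping.

## The correlation statistic

For each integer lag $\ell \in [0, 30]$ ms, $r(\ell)$ is the Pearson
correlation between the envelope and the PSTH delayed by $\ell$. The
reported $R$ is the peak inside the 5–20 ms acceptance window — the
physiological range of acoustic ICC latencies; the `in_window` flag records
whether the global peak also fell inside that window (it is never silently
replaced). Ties break toward the smaller lag; the lag grid is the common
1-ms bin width, with no sub-bin interpolation.

Pearson normalization is the only reading consistent with max-normalized
inputs and "1 means a perfect match": it is exactly invariant to affine
transforms of either series, so normalization choices cannot change $R$.

Summaries per (call, level, model variant) report n, median $R$ and the
fraction of cases with $R \ge 0.85$, the high-follower criterion
(inclusive). Cross-call overlap asks, among sites high on one call, how many
are high on all or at least one of the others; cross-level consistency asks
how many sites with data at 40/50/60 dB SPL are high at all three. The
linear-path-only variant (compression removed) is compared against the full
model with a two-sided Wilcoxon rank-sum test — exact for tie-free samples
of at most 20 each, normal approximation with continuity and tie correction
otherwise.

## What the synthetic data emulate — and what they do not

`synth_call()` produces three archetypes: a harmonic stack whose
fundamental sweeps 400 → 1200 Hz under slow amplitude modulation
("TSV"-like), noise bursts flanking a steady harmonic segment ("BH"-like),
and a train of eight short broadband bursts ("BT"-like). All pass through
the experimental conditioning chain (500 Hz–40 kHz bandpass, 25-ms
raised-cosine ramps, 50-ms pads) at 97.5 kHz. Because the sweep starts at
the stimulus band edge, the lowest part of the fundamental is attenuated at
onset — the spectrogram ridge briefly rides harmonic 2; tests and analyses
that track the sweep do so within the fundamental's in-band portion.

`synth_spike_trains()` draws per-1-ms-bin Poisson counts with rate
$r(t) = r_{spont} + g\,e(t - d)^{\gamma}$ for followers (delay $d$,
optional power law $\gamma$), a 30-ms onset burst for onset-only units, and
the follower formula on a seeded permutation of the envelope bins for
scrambled controls — the permutation preserves the marginal rate
distribution exactly, isolating temporal locking as the only difference.
Defaults are 20 trials, spontaneous rate 8 spikes/s and gain 80 spikes/s
per unit envelope. Every generator is a pure function of its parameters and
seed, and the global RNG stream is left untouched.

These units are deliberately minimal: no biophysics, no adaptation, no
level-dependent response nonlinearities beyond the exponent knob, and no
model of the real heterogeneity of ICC response classes. Passing tests
therefore demonstrate that the *pipeline* recovers what was put in — lags,
tuning, envelope locking — not that real ICC neurons behave like the
simulator.

### The correlation ceiling of a Poisson follower

A useful closed form when interpreting simulated $R$ values: for a follower
with signal variance $\sigma_s^2$ across bins and residual (Poisson plus
spontaneous-subtraction) variance $\sigma_n^2$ after smoothing,
$\mathbb{E}[R] \approx \sqrt{\sigma_s^2/(\sigma_s^2+\sigma_n^2)}$. At the
default rates (gain 80, spontaneous 8 spikes/s, 20 trials) this ceiling is
about 0.88 for the broadband-transient envelope: subtracting the per-bin
spontaneous mean scaled to the driven trial count — the PSTH definition
used throughout — contributes an appreciable share of $\sigma_n^2$.
Simulated follower medians just below 0.9 are thus the expected noise
ceiling of the study conditions, not a recovery failure; raising the driven
rate (or trial count) raises the ceiling.

## Numerical and design choices

* Zero-phase (forward–backward) 4th-order Butterworth for the 500 Hz–40 kHz
  stimulus conditioning: the filter family is not dictated by the
  experimental description, and zero phase avoids distorting envelope
  timing, which is the analysis target. Band edges that reach Nyquist are
  clipped to 0.95 × Nyquist with a warning.
* Level calibration scales by one constant so the peak of a 20-ms sliding
  RMS window (1-sample hop) matches the target re 20 µPa.
* The 1-ms binning uses within-bin means; bin $k$ covers $[k, k+1)$ ms.
* The 10-bin boxcar is centred with shrinking edge windows (no artificial
  lag is introduced into the correlation).
* Degenerate inputs fail loudly: all-zero stimuli cannot be calibrated or
  normalized; constant series cannot be correlated; untuned maps raise
  rather than return a meaningless centroid; a spontaneous PSTH with zero
  variance passes the validity filter only with a logged warning.
* `run_pipeline()` validates its config schema before any computation,
  derives every seed deterministically from the master seed, caches one
  envelope per (call, level, BF, variant), tags every output file with the
  config hash, and logs every threshold applied and every excluded case.

The worked examples and the shipped demonstration configuration use
500-ms calls at 97.5 kHz, 30 sites spanning 1–16 kHz, three levels
(40/50/60 dB SPL) and 20 trials — sizes chosen so a complete run finishes
in about a minute on a laptop while leaving every summary statistic
well-populated.

## Known limitations

* DRNL coefficients are a faithful family, not a certified port of any
  specific published fit; treat absolute channel amplitudes as model
  estimates and override coefficients from YAML where a better fit exists.
* The automated threshold and BF rules replace judgments that were
  originally visual; both are parameterized and documented rather than
  hidden.
* Inner-hair-cell and auditory-nerve stages are deliberately absent: the
  model output is basilar-membrane velocity, treated as the input to a
  single black box ending at the ICC.
* Lag estimation needs envelope landmarks. Transient calls localize lags to
  the bin; quasi-periodic envelopes (the TSV archetype) make the
  correlation peak ambiguous across periods, which is a property of the
  stimulus, not of the estimator.
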