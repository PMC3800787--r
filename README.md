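# envfollow

Quantifying how well auditory midbrain neurons follow the
frequency-specific envelope of natural sounds, using a guinea-pig
peripheral ear model.

## The problem

Multi-unit spiking recorded in the central nucleus of the inferior
colliculus (ICC) can only be compared meaningfully to the stimulus envelope
*after* the outer/middle ear and cochlea have filtered, compressed and
frequency-decomposed the sound. `envfollow` implements that comparison as a
reusable pipeline, for auditory physiologists and auditory-prosthesis
researchers who need a principled "did this site follow the envelope?"
statistic per recording site:

1. **Peripheral model** — calibrated sound pressure (Pa) → middle-ear
   Butterworth cascade (2nd order 4–25 kHz · 3rd order 700 Hz–30 kHz,
   ×1.4·10⁻¹⁰ to stapes velocity) → a dual-resonance non-linear (DRNL)
   cochlear channel per best frequency (BF): a linear path
   (gain → 3 gammatones → 4 lowpasses) summed with a compressive path
   (3 gammatones → broken stick `sign(x)·min(a|x|, b|x|^ν)` →
   3 gammatones → 4 lowpasses).
2. **Envelope** — Hilbert envelope of the channel, 1-ms bins, 10-ms sliding
   average (passes fluctuations up to ≈100 Hz), max-normalized.
3. **Neural side** — spike detection at −3.5 SD on 300–3000 Hz bandpassed
   traces (negative troughs only), driven PSTHs (total minus scaled mean
   spontaneous, 1-ms bins), frequency response maps and log₂-centroid BF
   estimates, and a validity filter (> 20 bins above 4 × spontaneous SD).
4. **The statistic** — lag-windowed peak Pearson correlation
   `R = max_{ℓ∈[5,20] ms} cor(env(t), psth(t+ℓ))`, with the global-peak
   location flagged, plus summaries: median R and fraction ≥ 0.85 per
   (call, level, model variant), cross-call overlap, cross-level
   consistency, and linear-path vs full-model Wilcoxon rank-sum
   comparisons.
5. **Synthetic ground truth** — seeded generators for three vocalization
   archetypes (harmonic upward sweep, broadband+harmonic, broadband burst
   train) and envelope-driven Poisson units (followers with known
   conduction delay, onset-only and scrambled-envelope controls), so every
   stage is testable without animal data.

See `vignettes/envelope-following.Rmd` for the model details, parameter
tables and design rationale.

## Worked example

Synthesize a broadband burst-train call, compute the 8-kHz channel
envelope, simulate a follower site with a 12-ms conduction delay, and ask
whether the pipeline recovers it:

```r
library(envfollow)

stim <- synth_call("BT", duration_ms = 500, seed = 11)
stim <- calibrate_level(stim, 60)
stim
#> <acoustic_stimulus> BT: 600.0 ms at 97500 Hz, level 60 dB SPL

env <- drnl_output(stim, bf_hz = 8000)
env
#> <envelope_trace> BF 8000 Hz, 600 x 1-ms bins from t0=0 ms, max-normalized

unit <- unit_spec("follower", gain = 80, delay_ms = 12, spont_rate = 8)
trains <- synth_spike_trains(env, unit, n_trials = 20, seed = 5)
psth <- build_psth(trains$driven, trains$spont, length(env$values), bf_hz = 8000)
spont_psth <- build_psth(trains$spont, NULL, length(env$values))
validity_filter(psth, spont_psth, stim_window = c(50, 570))
#> [1] TRUE

res <- peak_correlation(condition_psth(psth), env, call = "BT", level_db_spl = 60)
res[, c("r_peak", "lag_ms", "in_window", "valid")]
#>      r_peak lag_ms in_window valid
#> 1 0.9260231     11      TRUE  TRUE
```

The site passes the activity filter, correlates at R = 0.93 with the
channel envelope, and the correlation peak sits at 11 ms — the simulated
12-ms delay recovered to the 1-ms bin, inside the 5–20 ms physiological
window. R ≥ 0.85 marks a "high follower"; scrambled-envelope controls at
identical firing rates score near 0.

A complete study (3 calls × 3 levels × 30 sites × 2 model variants) runs
from one config:

```r
out <- run_pipeline(demo_config(seed = 1), out_dir = "results-demo")
out$summary   # n, median R, fraction >= 0.85, BF range per condition
```

or from the shell via `inst/scripts/envfollow-run.R --demo --seed 1 --out
results-demo`.

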