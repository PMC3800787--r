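Package: envfollow
Title: Envelope-Following Analysis of Auditory Midbrain Responses with a
    Peripheral Ear Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well spiking activity in the central
    nucleus of the inferior colliculus (ICC) follows the frequency-specific
    envelope of vocalization stimuli. A guinea-pig peripheral ear model
    (middle-ear Butterworth cascade plus a dual-resonance non-linear, DRNL,
    cochlear filterbank) converts calibrated sound pressure into per-best-
    frequency basilar-membrane velocity; Hilbert envelopes at 1-ms resolution,
    smoothed with a 10-ms sliding average and max-normalized, are compared to
    driven post-stimulus time histograms by lag-windowed peak cross-correlation.
    Includes spike detection from extracellular traces, frequency-response-map
    and best-frequency estimation, population spectrogram panels, summary
    statistics of correlation values, and a fully seeded synthetic-data module
    (call-like stimuli and inhomogeneous-Poisson unit simulators) so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
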