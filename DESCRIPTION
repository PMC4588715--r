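Package: spikefield
Title: Spike-Field Coherence and Psychophysics for Rapid Perceptual Learning Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Block-by-block analysis of spike-field synchronization and
    behavioral discrimination in visual cortical learning sessions.
    Implements spike-triggered average (STA) based spike-field coherence
    with hybrid Hanning/Slepian multitaper spectra, coherence z-transforms,
    spike-count equalization and trial-shuffle null controls; band-specific
    equiripple FIR filtering with Hilbert instantaneous phase and circular
    statistics (Rayleigh, omnibus, Kuiper, common-median tests); Weibull
    psychometric fitting with false-alarm-corrected 75% thresholds, sliding
    learning curves and microsaccade screening; and a synthetic-session
    generator with von Mises phase-coupled spiking for parameter-recovery
    testing of the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
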