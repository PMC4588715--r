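# spikefield

Block-by-block analysis of spike-field synchronization and behavioral
discrimination for rapid perceptual-learning sessions in visual cortex.

During a single session, a subject discriminates a briefly flashed target
image from a rotated test image while single-unit spikes and local field
potentials (LFPs) are recorded. The question this package serves: does
behavioral improvement within the session go together with increased
phase locking between spikes and low-frequency (theta) LFP oscillations,
even when firing rates and LFP power do not change?

## What it computes

**Spike-field coherence (SFC).** For spikes of one unit and the LFP of one
channel, the spike-triggered average (STA) is the mean LFP segment in a
±150 ms window around each spike, and

    SFC(f) = power spectrum of STA / mean power spectrum of the segments

computed with a hybrid multitaper scheme (single Hanning taper at ≤ 30 Hz,
K = 2TW − 1 = 7 Slepian tapers above, TW = 4). SFC is 0 for no locking, 1
for perfect locking, independent of LFP scale, and compared across
96-trial blocks only after equalizing spike counts by random subsampling.
A z-transform `z = β(−(V−2) ln(1−C²) − β)`, β = 1.15, V = spikes ×
tapers, puts coherence on an approximately standard-normal null scale.
Trial-shuffle surrogates (median of 100 permutations of the trial-to-LFP
assignment) separate genuine trial-by-trial coupling from stimulus-locked
structure.

**Phase locking.** Band-specific equiripple FIR filters (theta pass band
4–8 Hz with 3.5/8.5 Hz stop edges, 40 dB attenuation), Hilbert
instantaneous phase, spike-phase distributions in the 150–350 ms
post-stimulus windows, and circular statistics: Rayleigh Z = |Σe^{iθ}|²/n,
Hodges–Ajne omnibus, two-sample Kuiper, and the multi-sample
common-median test.

**Behavior.** Weibull psychometric fits
`P(Δθ) = 1 − (1 − FA) e^{−(Δθ/a)^b}` with the false-alarm rate FA fixed
at the observed zero-rotation error rate; the 75 %-correct threshold in
closed form `a (ln((1−FA)/0.25))^{1/b}`; per-block thresholds; a sliding
64-trial learning curve with exponential fit; match-trial strategy
controls; and 10 deg/s vector-velocity microsaccade screening with a
0.25 deg fixation-instability abort.

**Session statistics.** Per-pair block changes (Wilcoxon signed-rank,
Kruskal–Wallis), neuronal discriminability d′ = |μA − μB| / √((σA²+σB²)/2),
delay-period SFC in three 333 ms windows, and the cross-session Pearson
correlation between threshold change and mean theta-SFC change
(blocks 2–4 vs block 1).

**Synthetic sessions.** Since no public recordings accompany the analysis,
`generate_session()` builds full sessions with known ground truth: 1/f
background plus a band oscillation, spikes from a von Mises phase-coupling
model `r(t) = r₀ e^{κ cos(φ(t)−φ₀)} / I₀(κ)`, a Weibull observer, and eye
traces with injected microsaccades. `session_preset()` provides the
novel / familiar / no-learning regimes used in end-to-end tests.

## Worked example

```r
library(spikefield)

preset <- session_preset("novel", seed = 11)
sess   <- generate_session(preset$config, preset$profiles, preset$observer)
res    <- run_session(sess, seed = 5)
res
#> <session_result> 384 trials kept, 16 pair-band rows
#> block thresholds (deg): 19.84, 5.31, 6.32, 4.99
#> relative threshold change (blocks 2+ vs 1): -72.1%
#> relative theta SFC change: 164.3%
```

The printed lines are the session's two headline numbers. The block
thresholds come from Weibull fits per 96-trial block: the observer's
discrimination threshold falls from 19.8° in block 1 to about 5° once
learning saturates (a 72 % relative decrease). The theta SFC change is
the mean over spike–LFP pairs of the relative change in 4–8 Hz coherence
in blocks 2–4 versus block 1, computed from equalized spike counts in the
150–350 ms post-stimulus windows; in this `novel` regime the generator
steps the coupling up after block 1 and the pipeline recovers a large
positive change. `res$pairs` holds the per-pair, per-block band SFC and z
values, `res$phase$per_block` the Rayleigh/omnibus phase-locking tests,
and `res$delay` the delay-period SFC, which shows no block effect because
the preset couples spikes to the field only during stimulus epochs.

For a cohort, `run_cohort(list_of_sessions)` returns per-session changes
and their Pearson correlation (threshold change vs theta-SFC change).

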