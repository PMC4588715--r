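---
title: "Spike-field coherence and behavior in learning sessions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-field coherence and behavior in learning sessions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefield)
```

## What the package computes

`spikefield` analyzes sessions in which a subject discriminates rotated
images while single-unit spikes and local field potentials (LFPs) are
recorded. The scientific question it serves is whether rapid perceptual
learning within a session is accompanied by increased synchronization
between spikes and low-frequency (theta) field oscillations, block by
block, and whether that increase tracks the behavioral improvement.

The pipeline has five stages, each usable on its own:

1. **LFP conditioning** — broadband 0.5-100 Hz zero-phase Butterworth
   filtering, a 60 Hz elliptic notch, per-trial artifact rejection (a trial
   is discarded iff more than 3 samples fall outside its own mean ± 4 SD),
   hybrid multitaper power spectra, band power, and ERPs.
2. **Spike-field coherence (SFC)** — the spike-triggered average (STA) of
   the LFP in ±150 ms windows, with SFC defined as the power spectrum of
   the STA divided by the average power spectrum of the contributing LFP
   segments. SFC is 0 for no phase locking and 1 for perfect locking, is
   exactly invariant to LFP rescaling, and is compared across blocks only
   after spike counts are equalized by random subsampling.
3. **Phase locking** — band-specific equiripple FIR filtering, Hilbert
   instantaneous phase, spike-phase distributions in the 150-350 ms
   post-stimulus windows, and circular statistics (Rayleigh,
   Hodges-Ajne omnibus, two-sample Kuiper, common-median tests).
4. **Behavior** — Weibull psychometric fits
   `P(dtheta) = 1 - (1 - FA) exp(-(dtheta/a)^b)` with the false-alarm rate
   fixed to the observed zero-rotation error rate, the 75%-correct
   threshold in closed form, 96-trial block thresholds, a sliding 64-trial
   learning curve with an exponential fit, match-trial strategy controls,
   and velocity-threshold microsaccade screening.
5. **Session statistics** — block-change tests (Wilcoxon signed-rank,
   Kruskal-Wallis), delay-period SFC in three equal windows, and the
   cross-session Pearson correlation between the change in threshold and
   the mean change in theta SFC (blocks 2-4 versus block 1).

Because no public recordings accompany this analysis, the package ships a
synthetic-session generator with known ground truth; every stage has
parameter-recovery tests against it.

## The synthetic generator and what it does (not) emulate

A generated session has 4 blocks of 96 trials (48 match trials and 12
non-match trials per non-zero rotation of {3, 5, 10, 20} degrees), with
500 ms fixation, a 300 ms target, a 1000 ms delay (optionally jittered
800-1200 ms), a 300 ms test, and traces extending 100 ms past test offset
at 1 kHz.

* **LFP**: a sinusoid at the profile's oscillation frequency (default 6 Hz,
  random starting phase per trial) over 1/f^alpha Gaussian background
  noise (alpha = 1 by default). Real LFPs have richer, nonstationary
  spectra; the generator's background is stationary by design so that
  coherence ground truth is exact.
* **Spiking**: an inhomogeneous Bernoulli process on the 1 kHz grid with
  rate `base_rate * exp(kappa cos(phi - phi0)) / I0(kappa)`, the standard
  von Mises phase-coupling model. `kappa` is the interpretable ground
  truth: 0 decouples spikes from the field, and the normalization keeps
  the mean rate at `base_rate` for every `kappa`, which is what makes
  rate-invariance tests meaningful. The modulating phase is the Hilbert
  phase of the band-passed LFP (a zero-phase Butterworth inside the
  generator, deliberately distinct from the analysis module's equiripple
  FIR path so the two never share code).
* **Behavior**: a Weibull observer with per-block `FA`, `a`, `b`.
* **Eye traces**: low-passed drift (~0.02 deg SD) plus Poisson
  microsaccades realized as 10 ms linear steps, with the injected event
  list returned as ground truth.

All randomness flows from one session seed through `split_seed()`, which
hashes the seed with a stream label and an index; any single trial can be
regenerated in isolation.

The `session_preset()` regimes fix the study conditions for end-to-end
tests: `novel` steps theta coupling up after block 1 (kappa 0.5 to 0.6)
while the observer's offset falls 17 to 4.2 degrees; `familiar` holds
kappa at 0.6 with a low flat threshold; `no_learning` holds kappa at 0.5
with a high flat threshold. Coupling is confined to the two stimulus
epochs, so the delay period carries no block effect. The kappa step
corresponds to roughly a 40% increase in the squared generative phase
locking; the realized SFC step measured by the pipeline is larger
(on the order of +100%). We kept that deliberately stronger-than-monkey
effect because desk-scale tests observe a handful of spike-LFP pairs
rather than hundreds, and the end-to-end assertions are qualitative
(step present versus absent), not effect-size reproductions. Passing
these tests shows the pipeline recovers known coupling structure from
realistic noise; it does not certify performance on real recordings with
nonstationary backgrounds, electrode drift, or correlated noise across
channels.

## Multitaper settings

Spectra use ±150 ms windows (301 samples at 1 kHz, about 3.32 Hz native
resolution) stepped every 10 ms. Above 30 Hz the estimate averages K = 7
Slepian tapers (time-bandwidth product TW = 4, K = 2TW - 1); at and below
30 Hz a single Hanning taper is used, since seven tapers at TW = 4 would
smear ±13 Hz and obliterate the theta band. The Slepian sequences are
computed from the classical symmetric tridiagonal eigenproblem and cached.
Band power statistics are always taken on the native FFT grid of the
window — zero-padding is allowed for display but never for statistics,
which avoids interpolation artifacts. Two theta presets exist on purpose:
the power-band table uses 5-7 Hz, while SFC statistics use 4-8 Hz; both
are named explicitly (`power_bands()`, `sfc_bands()`) rather than silently
reconciled.

"Fourth order" for the broadband Butterworth filter is read as the
designed order before forward-backward application (effective order 8).
Artifact statistics are computed per trial and per channel because muscle
artifacts are trial-local.

## The SFC estimator and its z-transform

With segments `x_i` (the ±150 ms LFP around each usable spike; spikes
whose window would cross the trace edge are excluded rather than
zero-padded, since padding biases segment spectra), the estimate at
frequency f is

    SFC(f) = |mean_i X_i(f)|^2 / mean_i |X_i(f)|^2

per taper, averaged over tapers, where `X_i` is the tapered FFT. By
Cauchy-Schwarz this ratio lies in [0, 1] at every frequency for every
dataset — the bound is structural, not statistical. The segment spectra
are averaged as raw power (never dB) before dividing.

The SFC so defined is a squared-magnitude coherence: under the null its
expectation is 1/n for n independent segments, and for sparse spike
trains (one spike per window) it coincides *exactly* with the direct
multitaper point-process/field coherence `|S_xy|^2 / (S_xx S_yy)` at
single-taper frequencies. The test suite verifies that identity to
machine precision on 20 coupled fixtures (`pp_coherence()` is an
independent implementation: cross-spectra of binned spike trains, not a
power ratio). With denser trains the two estimators differ by the
neighbor-spike terms, which is why the equivalence fixtures enforce a
minimum inter-spike gap.

The variance-stabilizing transform is

    z = beta * ( -(V - 2) * log(1 - C^2) - beta ),  beta = 1.15,

applied with `C^2` equal to the SFC (i.e. `C` is magnitude coherence) and
degrees of freedom `V = n_spikes x n_tapers`. Three remarks, all
documented because they are decisions rather than givens:

* A common variant applies a square root to the log term before centering
  (`sqrt_q = TRUE`); the direct form is the default here, and a
  `dof_scale = 2` switch selects the alternative `2 n K` bookkeeping.
* Null calibration was checked by simulation (`simulate_null_z()`:
  homogeneous Poisson spikes on white noise, end to end through
  `compute_sfc()`). At single-taper frequencies the default convention is
  the closest to a unit-variance standard normal of the available
  variants (the sqrt variants give null variances near 0.26 and 0.51);
  its asymptotic null variance is beta^2 ~ 1.32, and sample variances
  from a few hundred replicates scatter widely around that because the
  underlying pivot is exponential-tailed.
* Above the 30 Hz crossover the `n x K` bookkeeping overstates the
  degrees of freedom of *this* estimator: averaging numerator and
  denominator over tapers leaves the null mean of SFC near 1/n, not
  1/(nK), so null z values at Slepian frequencies are biased upward.
  Theta-band inference — the band this analysis cares about — sits in the
  calibrated single-taper regime. The null-calibration check is therefore
  evaluated at a theta frequency (the 6.64 Hz grid point), with
  1 spike/s for 1000 s per replicate so that spike windows rarely
  overlap, the regime the asymptotics address.

Block comparisons equalize spike counts first (`subsample_spikes()`,
without replacement, down to the minimum over blocks) because the SFC
null level depends on n. The trial-shuffle control (`shuffle_control_sfc()`,
`shuffled_phase_z()`) permutes the trial-to-LFP assignment — each trial's
LFP used exactly once, fixed points allowed (a `derangement` flag exists;
the plain-permutation reading was chosen) — and summarizes 100 shuffles
by their median. Locking that survives the shuffle is stimulus-locked
rather than trial-specific.

## Band filters and phase

The phase path uses equiripple FIR specs per band (theta stop/pass edges
3.5-4 and 8-8.5 Hz; alpha 7-8 / 14-15; beta 13-14 / 30-31.5; gamma 28-30 /
80-82), 40 dB stopband attenuation, and 1 dB passband ripple ("1 ripple"
in the original description is non-standard phrasing; we read it as 1 dB).
A 0.5 Hz transition at 1 kHz needs a ~4500-tap equiripple design, which
is numerically out of reach of the Parks-McClellan implementation
available here (it destabilizes above roughly order 1000), so
`band_filter()` is multirate: zero-phase Butterworth anti-alias,
decimation (factor 10 for theta), `signal::remez()` design at the
decimated rate with the order set by the Kaiser estimate plus margin and
*verified* against the 40 dB target on a dense grid at design time, group
delay compensated exactly (linear-phase FFT convolution with reflection
padding), and cubic-spline interpolation back to 1 kHz. The overall
response is zero phase; the attenuation spec is also asserted in tests on
long sinusoid fixtures.

Instantaneous phase is the angle of the FFT-constructed analytic signal.
Spike phases are read at the nearest sample (at 1 kHz the worst-case
error at 8 Hz is under 0.026 rad, negligible against the effects of
interest). Because a trial is short relative to the theta filter's
impulse response, the session pipeline filters the concatenated trial
traces per channel and splits the phase series back per trial; tests of
filter-phase agreement with the generator's oscillator use long
continuous fixtures (circular correlation > 0.95 required, > 0.999
observed on noiseless data).

For the uniformity tests, the omnibus test is the Hodges-Ajne variant
(exact p for n <= 50, the standard large-sample approximation otherwise);
the original description names only "Omnibus", so the choice is stated
here rather than inferred. The multi-sample comparison is the
common-median chi-squared test with the pooled circular median taken as
the P-median over observed angles; it is pinned by fixture-based tests
(duplicated samples non-significant, opposed preferred phases detected),
not by library identity. Simulated type-I rates at n = 200 are 4.6%
(Rayleigh) and 3.6% (omnibus) at the nominal 5%.

## Behavioral fitting choices

`fit_weibull()` fixes FA at the observed false-alarm rate — the formula
treats FA as data, not a parameter — and estimates `a`, `b` by
Levenberg-Marquardt least squares on the per-rotation accuracies; a
binomial-likelihood option weighted by trial counts exists and agrees
closely on clean data. The threshold is the exact closed-form inversion
`a * (log((1-FA)/0.25))^(1/b)`, so `P(threshold) = 0.75` to numerical
precision. Degenerate (flat) curves and non-convergence are flagged and
the threshold withheld. The learning curve uses
`y(t) = y_inf + (y0 - y_inf) exp(-t/tau)`; only "exponential fit" was
specified, so the three-parameter saturating form was chosen as the
weakest assumption that can express both improvement and a flat curve.

The microsaccade velocity criterion is inclusive (>= 10 deg/s) because
the worked equivalence — 0.1 deg per 10 ms interval — sits exactly at
threshold. Events above 0.25 deg set the trial-abort flag.

Error trials are *included* in neural analyses by default (the original
procedure does not state an exclusion); `run_session(correct_only =
TRUE)` restricts to correct trials.

## Statistics and session-level summaries

Block-change inference on per-pair band values uses paired Wilcoxon
signed-rank tests of each later block (and of the blocks 2-4 mean)
against block 1 plus a Kruskal-Wallis omnibus; per-band p-values are
uncorrected by default with a Holm flag available, matching the original
per-band reporting. Relative change is computed per pair as
`(block_k - block_1)/block_1` and then averaged; the per-pair order was
chosen (the alternative per-session normalization is ambiguous in the
source) and is stated here. With fewer than 10 complete pairs only
descriptive summaries are produced. The cross-session statistic is the
Pearson correlation between the threshold change and the mean theta-SFC
change (blocks 2-4 vs 1); per-band breakdowns use the same form.

Delay-period SFC divides the delay into three equal windows; with a
jittered delay the windows are still thirds of the actual delay (a
truncated delay rescales with a warning).

## Numerical and degenerate-input conventions

* STA/SFC with zero usable spikes: `compute_sta()` returns an explicit
  empty result (`n_spikes = 0`, no trace) distinct from a zero trace;
  `compute_sfc()` errors; sliding-map windows without spikes are masked
  `NA`; frequencies with zero segment power are masked `NA`.
* A block with zero spikes raises a condition of class
  `spikefield_empty_block`; the pipeline catches it and excludes the pair
  with a message.
* `z` at SFC = 1 is infinite and masked; `V <= 2` is rejected.
* Weibull fits report a `converged` flag; bounds `a <= 1e4`, `b <= 50`
  keep the optimizer out of the flat-likelihood region, and hitting them
  marks the fit degenerate.
* All filters are applied forward-backward (or as compensated
  linear-phase FIR), so no stage introduces phase shifts; the zero-phase
  property is tested via cross-correlation peak lags.

## Problem sizes used by the test and acceptance runs

Property suites run at sizes chosen to make their Monte-Carlo error small
relative to the asserted margins while keeping a full run modest: 1,000
random fixtures for the SFC bounds/scale-invariance battery, 20 sparse
coupled fixtures for the estimator-equivalence identity, 500+ spikes per
kappa level for monotonicity, 200 replicates of ~1,000 spikes x 1,000 s
for the null-z calibration, 100 simulated 960-trial observers for
Weibull recovery, and three full 384-trial sessions (two units x two
channels) for the end-to-end regime dissociation.

## Known limitations

* The generator's oscillation is a fixed-frequency sinusoid per trial;
  real theta is broadband and drifting, so absolute SFC levels here are
  optimistic.
* The z-transform's degrees-of-freedom bookkeeping is only calibrated at
  single-taper frequencies (see above); gamma-band z values should be
  interpreted as relative, not absolute.
* `pp_coherence()` is a validation tool, not a general coherence routine:
  it shares the spike-centered segmentation of the STA method by design.
* The plain-text session container stores full traces as CSV; it is meant
  for exchange and inspection, not for large-scale storage.
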