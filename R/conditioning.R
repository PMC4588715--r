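# LFP conditioning: filtering, artifact rejection, multitaper spectra,
# band power, and event-related potentials.

#' Construct an LFP trace
#'
#' A single channel's voltage series for one trial, sampled at `rate` Hz.
#' `t0` is the time of the first sample in seconds relative to target onset
#' (negative values lie in the fixation period).
#'
#' @param samples numeric vector of voltages (arbitrary units)
#' @param rate sampling rate in samples/s
#' @param t0 time of the first sample, s relative to target onset
#' @return an object of class `lfp_trace`
#' @export
lfp_trace <- function(samples, rate = 1000, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              length(x$samples), x$rate, x$t0,
              x$t0 + (length(x$samples) - 1) / x$rate))
  invisible(x)
}

#' Time axis of an LFP trace
#' @param trace an [lfp_trace()]
#' @return numeric vector of sample times in seconds
#' @export
lfp_time <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

as_lfp <- function(x, rate = 1000, t0 = 0) {
  if (inherits(x, "lfp_trace")) x else lfp_trace(x, rate = rate, t0 = t0)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filtering with a Butterworth design applied forward and
#' backward ([signal::filtfilt()]) so the output has zero phase shift.
#' `order` is the designed filter order before the two-pass application
#' (the effective magnitude response is that of a filter of twice the
#' order). The broadband conditioning default is 0.5-100 Hz, order 4.
#'
#' @param trace an [lfp_trace()] (or numeric vector at 1 kHz)
#' @param low,high passband edges in Hz, `0 < low < high < rate/2`
#' @param order designed Butterworth order
#' @return filtered [lfp_trace()] with the same length and `t0`
#' @export
lfp_bandpass <- function(trace, low = 0.5, high = 100, order = 4) {
  trace <- as_lfp(trace)
  ny <- trace$rate / 2
  if (!(low > 0 && low < high && high < ny)) {
    stop("passband must satisfy 0 < low < high < rate/2")
  }
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  out <- signal::filtfilt(bf, trace$samples)
  lfp_trace(out, rate = trace$rate, t0 = trace$t0)
}

#' 60 Hz elliptic notch filter
#'
#' Removes mains interference with a band-stop elliptic design (order 4,
#' 0.1 dB peak-to-peak passband ripple, 40 dB stopband attenuation) applied
#' forward and backward for zero phase shift. The stop band is centered on
#' 60 Hz and narrow enough that components at or below 55 Hz and at or
#' above 65 Hz pass essentially unchanged.
#'
#' @param trace an [lfp_trace()] (or numeric vector at 1 kHz)
#' @param center line frequency in Hz
#' @param halfwidth half-width of the stop band in Hz
#' @return filtered [lfp_trace()]
#' @export
lfp_notch <- function(trace, center = 60, halfwidth = 2) {
  trace <- as_lfp(trace)
  if (trace$rate <= 2 * center) stop("sampling rate too low for the notch")
  ny <- trace$rate / 2
  ef <- signal::ellip(4, Rp = 0.1, Rs = 40,
                      W = c(center - halfwidth, center + halfwidth) / ny,
                      type = "stop")
  out <- signal::filtfilt(ef, trace$samples)
  lfp_trace(out, rate = trace$rate, t0 = trace$t0)
}

#' Reject LFP trials with outlier artifacts
#'
#' A trace is discarded iff it has more than `max_outliers` samples outside
#' its own mean +/- `n_sd` standard deviations (both statistics per trace,
#' so that trial-local muscle artifacts are caught). The returned partition
#' of trace indices is exhaustive and disjoint.
#'
#' @param traces list of [lfp_trace()] objects or numeric vectors, or a
#'   matrix with one trace per row
#' @param n_sd outlier threshold in SD units
#' @param max_outliers maximum tolerated number of outlier samples
#' @return list with integer index vectors `kept` and `discarded`
#' @export
reject_artifacts <- function(traces, n_sd = 4, max_outliers = 3) {
  if (is.matrix(traces)) traces <- asplit(traces, 1)
  if (length(traces) < 1L) stop("need at least one trace")
  bad <- vapply(traces, function(tr) {
    x <- if (inherits(tr, "lfp_trace")) tr$samples else as.numeric(tr)
    if (length(x) == 0L) stop("empty trace")
    sum(abs(x - mean(x)) > n_sd * sd(x)) > max_outliers
  }, logical(1))
  list(kept = which(!bad), discarded = which(bad))
}

#' Number of Slepian tapers for a time-bandwidth product
#'
#' `K = 2 TW - 1`, the largest taper count that preserves the spectral
#' concentration of the Slepian sequences (e.g. TW = 4 gives K = 7).
#'
#' @param TW time-bandwidth product, `>= 1`
#' @return integer taper count
#' @export
taper_count <- function(TW) {
  if (!is.numeric(TW) || length(TW) != 1L || TW < 1) stop("TW must be >= 1")
  as.integer(round(2 * TW - 1))
}

# cache for Slepian taper matrices keyed by "n_TW_K"
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `K` Slepian sequences of length `n` with
#' time-bandwidth product `TW` from the classical symmetric tridiagonal
#' eigenproblem (the eigenvectors of the tridiagonal matrix commuting with
#' the concentration operator). Tapers are unit-energy, mutually
#' orthonormal columns, signed so that symmetric tapers have positive mean.
#'
#' @param n taper length in samples
#' @param TW time-bandwidth product
#' @param K number of tapers (default `2 TW - 1`)
#' @return an `n x K` matrix, one taper per column
#' @export
dpss_tapers <- function(n, TW = 4, K = taper_count(TW)) {
  stopifnot(n >= 2, K >= 1, K < n)
  key <- paste(n, TW, K, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  W <- TW / n
  t <- 0:(n - 1)
  dv <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- dv
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) if (sum(v[, k]) < 0) v[, k] <- -v[, k]
  .taper_cache[[key]] <- v
  v
}

# unit-energy Hanning taper of length n
hanning_taper <- function(n) {
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  h / sqrt(sum(h^2))
}

#' Multitaper configuration
#'
#' Spectral-estimation settings shared by the LFP power and spike-field
#' coherence analyses: Slepian tapers (`K = 2 TW - 1`) are used above the
#' `crossover` frequency and a single Hanning taper at and below it, within
#' +/- `window_half` second analysis windows stepped every `step` seconds.
#'
#' @param TW time-bandwidth product of the Slepian family
#' @param window_half half window length in seconds (window = 2*window_half)
#' @param step sliding-window step in seconds
#' @param crossover frequency (Hz) at and below which the single Hanning
#'   taper is used; Slepian tapers apply strictly above it
#' @param rate sampling rate in samples/s
#' @return an object of class `mt_config`
#' @export
mt_config <- function(TW = 4, window_half = 0.150, step = 0.010,
                      crossover = 30, rate = 1000) {
  stopifnot(TW >= 1, window_half > 0, step > 0, crossover >= 0, rate > 0)
  structure(list(TW = TW, K = taper_count(TW), window_half = window_half,
                 step = step, crossover = crossover, rate = rate),
            class = "mt_config")
}

# expected segment length (odd, centered window) for a config
mt_segment_length <- function(cfg) as.integer(round(2 * cfg$window_half * cfg$rate)) + 1L

# per-taper two-sided power |FFT(h*x)|^2 for a matrix of tapers; returns
# n_freq x K matrix for a single segment
tapered_power <- function(x, tapers) {
  F <- mvfft(tapers * x)
  Mod(F)^2
}

#' Hybrid multitaper power spectral density of one segment
#'
#' One-sided PSD of a single analysis segment: average over the `K` Slepian
#' tapers for frequencies above the crossover, single Hanning taper at and
#' below it. Unit-energy tapers and density scaling `2 |X|^2 / rate` (DC and
#' Nyquist not doubled) so that the PSD of unit-variance white noise
#' integrates to about 1 over the one-sided band.
#'
#' @param segment numeric vector or [lfp_trace()] of length
#'   `2*window_half*rate + 1`
#' @param cfg an [mt_config()]
#' @return object of class `power_spectrum`: list with `frequencies` (Hz),
#'   `power`, and `n_tapers` per frequency
#' @export
multitaper_psd <- function(segment, cfg = mt_config()) {
  x <- if (inherits(segment, "lfp_trace")) segment$samples else as.numeric(segment)
  n <- length(x)
  if (n != mt_segment_length(cfg)) {
    stop(sprintf("segment length %d does not match the configured window (%d samples)",
                 n, mt_segment_length(cfg)))
  }
  slep <- dpss_tapers(n, cfg$TW, cfg$K)
  han <- hanning_taper(n)
  p_slep <- rowMeans(tapered_power(x, slep))
  p_han <- tapered_power(x, matrix(han, ncol = 1))[, 1]
  freqs <- (0:(n - 1)) * cfg$rate / n
  keep <- freqs <= cfg$rate / 2
  freqs <- freqs[keep]
  use_han <- freqs <= cfg$crossover
  pw <- ifelse(use_han, p_han[keep], p_slep[keep])
  scale <- rep(2 / cfg$rate, length(freqs))
  scale[freqs == 0 | freqs == cfg$rate / 2] <- 1 / cfg$rate
  structure(list(frequencies = freqs,
                 power = pw * scale,
                 n_tapers = ifelse(use_han, 1L, cfg$K)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d frequencies, %.2f-%.2f Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Frequency band definition
#'
#' @param name band label
#' @param low,high band edges in Hz, `low < high`
#' @return object of class `band_definition`
#' @export
band_definition <- function(name, low, high) {
  if (!(low < high)) stop("band must have low < high")
  structure(list(name = name, low = low, high = high), class = "band_definition")
}

#' Canonical frequency-band presets
#'
#' `power_bands()` returns the band set used for LFP power summaries
#' (theta 5-7, alpha 8-13, beta 15-30, gamma 35-80 Hz). `sfc_bands()`
#' returns the set used for spike-field coherence statistics, which names
#' theta as 4-8 Hz; the two theta presets are deliberately distinct and
#' both exposed.
#'
#' @return named list of [band_definition()] objects
#' @export
power_bands <- function() {
  list(theta = band_definition("theta", 5, 7),
       alpha = band_definition("alpha", 8, 13),
       beta = band_definition("beta", 15, 30),
       gamma = band_definition("gamma", 35, 80))
}

#' @rdname power_bands
#' @export
sfc_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta = band_definition("beta", 15, 30),
       gamma = band_definition("gamma", 35, 80))
}

#' Mean power within a frequency band
#'
#' Mean of the spectrum over the native frequency-grid points falling in
#' `[low, high]` (inclusive). Statistics are always taken on the native
#' grid; no interpolation or zero-padding is applied.
#'
#' @param spectrum a `power_spectrum` (from [multitaper_psd()])
#' @param band a [band_definition()]
#' @return scalar mean band power
#' @export
band_power <- function(spectrum, band) {
  idx <- spectrum$frequencies >= band$low & spectrum$frequencies <= band$high
  if (!any(idx)) stop(sprintf("band %s [%g, %g] contains no grid frequencies",
                              band$name, band$low, band$high))
  mean(spectrum$power[idx])
}

#' Normalize block band powers to the first block
#'
#' Given per-channel, per-band, per-block mean powers, divides each value by
#' the same channel/band's block-1 value, so block 1 is exactly 1 by
#' construction. Channels with non-positive block-1 power in any band are
#' excluded with a message.
#'
#' @param powers data.frame with columns `channel`, `band`, `block`, `power`
#' @return data.frame with an added `power_rel` column (excluded channels
#'   dropped); attribute `excluded` lists dropped channels
#' @export
normalize_power <- function(powers) {
  stopifnot(all(c("channel", "band", "block", "power") %in% names(powers)))
  key <- interaction(powers$channel, powers$band, drop = TRUE)
  ref <- vapply(split(powers, key), function(d) {
    d$power[d$block == min(d$block)][1]
  }, numeric(1))
  bad_keys <- names(ref)[!is.finite(ref) | ref <= 0]
  excluded <- unique(powers$channel[as.character(key) %in% bad_keys])
  if (length(excluded)) {
    message("excluding channel(s) with non-positive first-block power: ",
            paste(excluded, collapse = ", "))
    keep <- !(powers$channel %in% excluded)
    powers <- powers[keep, , drop = FALSE]
    key <- interaction(powers$channel, powers$band, drop = TRUE)
  }
  powers$power_rel <- powers$power / ref[as.character(key)]
  attr(powers, "excluded") <- excluded
  powers
}

#' Event-related potential per block
#'
#' Pointwise mean of artifact-free LFP traces across trials, aligned to the
#' named stimulus onset (`target` keeps the native time base; `test` shifts
#' it so the test stimulus onset is time zero).
#'
#' @param traces list of [lfp_trace()] objects (equal length, equal `t0`)
#' @param alignment `"target"` or `"test"`
#' @param test_onset test stimulus onset, s relative to target onset
#' @return an [lfp_trace()] holding the mean trace
#' @export
compute_erp <- function(traces, alignment = c("target", "test"),
                        test_onset = 1.3) {
  alignment <- match.arg(alignment)
  if (length(traces) < 1L) stop("no traces to average")
  mat <- do.call(rbind, lapply(traces, function(tr) as_lfp(tr)$samples))
  tr1 <- as_lfp(traces[[1]])
  t0 <- if (alignment == "target") tr1$t0 else tr1$t0 - test_onset
  lfp_trace(colMeans(mat), rate = tr1$rate, t0 = t0)
}
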