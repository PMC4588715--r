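# Spike-triggered averages, spike-field coherence, z-transform and
# shuffle controls.

# Extract the +/- window_half LFP segment around each usable spike.
# A spike is usable iff its full segment lies inside the trace and, when an
# analysis window is given, the spike time falls inside it. Returns a list
# with the segment matrix (n_spikes x n_samples) and the spike times used.
spike_segments <- function(spikes, lfp, window_half = 0.150,
                           analysis_window = NULL) {
  lfp <- as_lfp(lfp)
  spikes <- sort(as.numeric(spikes))
  half_n <- as.integer(round(window_half * lfp$rate))
  n <- length(lfp$samples)
  idx <- as.integer(round((spikes - lfp$t0) * lfp$rate)) + 1L
  ok <- idx - half_n >= 1L & idx + half_n <= n
  if (!is.null(analysis_window)) {
    ok <- ok & spikes >= analysis_window[1] & spikes <= analysis_window[2]
  }
  idx <- idx[ok]
  if (length(idx) == 0L) {
    return(list(segments = NULL, times = numeric(0), half_n = half_n))
  }
  seg <- matrix(lfp$samples[outer(idx, (-half_n):half_n, "+")],
                nrow = length(idx))
  list(segments = seg, times = spikes[ok], half_n = half_n)
}

# pool segments over one or several (spikes, lfp) trial pairs
pooled_segments <- function(spikes, lfp, window_half, analysis_window) {
  if (!is.list(spikes) || inherits(spikes, "lfp_trace")) spikes <- list(spikes)
  if (inherits(lfp, "lfp_trace") || !is.list(lfp)) lfp <- list(as_lfp(lfp))
  if (length(spikes) != length(lfp)) {
    stop("spikes and lfp must have the same number of trials")
  }
  pieces <- mapply(function(s, l) {
    spike_segments(s, l, window_half = window_half,
                   analysis_window = analysis_window)
  }, spikes, lfp, SIMPLIFY = FALSE)
  segs <- do.call(rbind, lapply(pieces, `[[`, "segments"))
  list(segments = segs,
       times = unlist(lapply(pieces, `[[`, "times")),
       half_n = pieces[[1]]$half_n)
}

#' Spike-triggered average of the LFP
#'
#' Pointwise mean of the LFP segments centered +/- `window_half` seconds on
#' each usable spike. Spikes whose segment would cross the trace edge are
#' excluded (never zero-padded). With no usable spike, an empty result
#' (`n_spikes = 0`, `trace = NULL`) is returned, distinct from a numeric
#' zero trace.
#'
#' @param spikes numeric vector of spike times (s, same time base as the
#'   trace), or a list of per-trial spike vectors
#' @param lfp an [lfp_trace()], or a list of per-trial traces matching
#'   `spikes`
#' @param analysis_window optional `c(t_start, t_end)`: only spikes inside
#'   it contribute
#' @param window_half half-window in seconds (window length
#'   `2*window_half*rate + 1` samples)
#' @return object of class `sta`: list with `trace` ([lfp_trace()] centered
#'   at lag 0), `n_spikes`, and `window_half`
#' @export
compute_sta <- function(spikes, lfp, analysis_window = NULL,
                        window_half = 0.150) {
  rate <- if (inherits(lfp, "lfp_trace")) lfp$rate else as_lfp(if (is.list(lfp)) lfp[[1]] else lfp)$rate
  p <- pooled_segments(spikes, lfp, window_half, analysis_window)
  if (is.null(p$segments)) {
    return(structure(list(trace = NULL, n_spikes = 0L,
                          window_half = window_half), class = "sta"))
  }
  structure(list(trace = lfp_trace(colMeans(p$segments), rate = rate,
                                   t0 = -window_half),
                 n_spikes = nrow(p$segments), window_half = window_half),
            class = "sta")
}

#' @export
print.sta <- function(x, ...) {
  cat(sprintf("<sta> n_spikes = %d, window +/- %g s%s\n", x$n_spikes,
              x$window_half, if (x$n_spikes == 0) " (empty)" else ""))
  invisible(x)
}

# hybrid numerator/denominator spectra for a segment matrix: returns
# one-sided frequency grid, STA power, mean segment power, taper counts
sfc_spectra <- function(segs, cfg) {
  n <- ncol(segs)
  tsegs <- t(segs)
  han <- hanning_taper(n)
  slep <- dpss_tapers(n, cfg$TW, cfg$K)
  Fh <- mvfft(tsegs * han)
  num_h <- Mod(rowMeans(Fh))^2
  den_h <- rowMeans(Mod(Fh)^2)
  num_s <- 0
  den_s <- 0
  for (k in seq_len(cfg$K)) {
    Fk <- mvfft(tsegs * slep[, k])
    num_s <- num_s + Mod(rowMeans(Fk))^2
    den_s <- den_s + rowMeans(Mod(Fk)^2)
  }
  freqs <- (0:(n - 1)) * cfg$rate / n
  keep <- freqs <= cfg$rate / 2
  use_han <- freqs[keep] <= cfg$crossover
  list(frequencies = freqs[keep],
       num = ifelse(use_han, num_h[keep], (num_s / cfg$K)[keep]),
       den = ifelse(use_han, den_h[keep], (den_s / cfg$K)[keep]),
       n_tapers = ifelse(use_han, 1L, cfg$K))
}

#' Spike-field coherence from the spike-triggered average
#'
#' SFC at each frequency is the power spectrum of the STA divided by the
#' average power spectrum of the LFP segments that formed the STA, using
#' the same hybrid Hanning/Slepian taper configuration for both. The value
#' lies in [0, 1]: 0 means no phase locking, 1 perfect locking. The measure
#' is exactly invariant under rescaling the LFP and, in expectation,
#' independent of the firing rate at fixed coupling. Frequencies where the
#' segment power vanishes are masked as `NA`.
#'
#' @inheritParams compute_sta
#' @param cfg an [mt_config()]
#' @return object of class `coherence_estimate`: `frequencies` (Hz), `sfc`,
#'   `n_spikes`, `n_tapers` (per frequency), and degrees of freedom `V =
#'   n_spikes * n_tapers` per frequency
#' @export
compute_sfc <- function(spikes, lfp, analysis_window = NULL,
                        cfg = mt_config()) {
  p <- pooled_segments(spikes, lfp, cfg$window_half, analysis_window)
  if (is.null(p$segments)) stop("no usable spikes for SFC")
  sp <- sfc_spectra(p$segments, cfg)
  sfc <- sp$num / sp$den
  bad <- !is.finite(sfc)
  if (any(bad)) sfc[bad] <- NA_real_
  n_spk <- nrow(p$segments)
  structure(list(frequencies = sp$frequencies,
                 sfc = sfc,
                 n_spikes = n_spk,
                 n_tapers = sp$n_tapers,
                 V = n_spk * sp$n_tapers),
            class = "coherence_estimate")
}

#' @export
print.coherence_estimate <- function(x, ...) {
  cat(sprintf("<coherence_estimate> %d frequencies, n_spikes = %d\n",
              length(x$frequencies), x$n_spikes))
  invisible(x)
}

#' Time-resolved spike-field coherence
#'
#' SFC computed in a 300-ms window sliding in `cfg$step` (default 10 ms)
#' increments over the trial, one [compute_sfc()] per window center.
#' Window centers run from `t_start + window_half` to `t_end - window_half`.
#' Windows without usable spikes give masked (`NA`) rows.
#'
#' @inheritParams compute_sfc
#' @param t_start,t_end analysis span in seconds (defaults: 100 ms before
#'   target onset to the end of the shortest trace)
#' @return list with `times` (window centers), `frequencies`, `map`
#'   (centers x frequencies SFC matrix) and `n_spikes` per center
#' @export
sliding_sfc <- function(spikes, lfp, cfg = mt_config(), t_start = -0.1,
                        t_end = NULL) {
  if (inherits(lfp, "lfp_trace") || !is.list(lfp)) lfp <- list(as_lfp(lfp))
  if (!is.list(spikes) || inherits(spikes, "lfp_trace")) spikes <- list(spikes)
  if (is.null(t_end)) {
    t_end <- min(vapply(lfp, function(l) l$t0 + (length(l$samples) - 1) / l$rate,
                        numeric(1)))
  }
  half <- cfg$window_half
  centers <- seq(t_start + half, t_end - half, by = cfg$step)
  nf <- length(multitaper_psd(numeric(mt_segment_length(cfg)) + 0, cfg)$frequencies)
  map <- matrix(NA_real_, length(centers), nf)
  nspk <- integer(length(centers))
  freqs <- NULL
  for (i in seq_along(centers)) {
    win <- c(centers[i] - half, centers[i] + half)
    est <- tryCatch(compute_sfc(spikes, lfp, analysis_window = win, cfg = cfg),
                    error = function(e) NULL)
    if (!is.null(est)) {
      map[i, ] <- est$sfc
      nspk[i] <- est$n_spikes
      freqs <- est$frequencies
    }
  }
  if (is.null(freqs)) {
    n <- mt_segment_length(cfg)
    freqs <- ((0:(n - 1)) * cfg$rate / n)
    freqs <- freqs[freqs <= cfg$rate / 2]
  }
  list(times = centers, frequencies = freqs, map = map, n_spikes = nspk)
}

#' Equalize spike counts across blocks
#'
#' Randomly subsamples (without replacement) each block's spikes down to the
#' minimum count over blocks, removing the spike-count bias of SFC when
#' blocks are compared. Blocks may be given as pooled numeric vectors or as
#' lists of per-trial vectors (structure is preserved). A block with zero
#' spikes makes the pair unusable and raises a condition of class
#' `spikefield_empty_block`.
#'
#' @param spike_sets list over blocks; each element a numeric vector of
#'   spike times or a list of per-trial spike vectors
#' @param seed integer seed making the subsample reproducible
#' @return list of the same shape with equalized counts
#' @export
subsample_spikes <- function(spike_sets, seed = 1) {
  counts <- vapply(spike_sets, function(b) {
    length(unlist(b, use.names = FALSE))
  }, integer(1))
  if (any(counts == 0L)) {
    stop(structure(class = c("spikefield_empty_block", "error", "condition"),
                   list(message = "block with zero spikes; pair excluded",
                        call = sys.call(-1))))
  }
  m <- min(counts)
  set.seed(seed)
  out <- vector("list", length(spike_sets))
  names(out) <- names(spike_sets)
  for (b in seq_along(spike_sets)) {
    blk <- spike_sets[[b]]
    if (is.list(blk)) {
      trial_id <- rep(seq_along(blk), lengths(blk))
      flat <- unlist(blk, use.names = FALSE)
      pick <- sort(sample.int(length(flat), m))
      kept <- split(flat[pick], factor(trial_id[pick], levels = seq_along(blk)))
      out[[b]] <- lapply(kept, as.numeric)
    } else {
      out[[b]] <- sort(sample(blk, m))
    }
  }
  out
}

#' z-transform of a coherence value
#'
#' Variance-stabilizing transform of magnitude coherence `C` with `V`
#' degrees of freedom: `z = beta * (-(V - 2) * log(1 - C^2) - beta)` with
#' `beta = 1.15`. Under the null hypothesis of no coupling, z behaves as an
#' approximately standard normal variate at single-taper frequencies, so z
#' counts how many standard deviations the observed coherence lies from
#' zero. `sqrt_q = TRUE` applies the square root to the log term before
#' centering (the conventional variant); the default follows the direct
#' form. Note the SFC of [compute_sfc()] is a squared-magnitude coherence:
#' use [z_transform_sfc()] for coherence estimates.
#'
#' @param C magnitude coherence in [0, 1)
#' @param V degrees of freedom (number of spikes times number of tapers)
#' @param beta transform constant
#' @param sqrt_q if `TRUE`, use `sqrt(-(V-2) log(1-C^2))` as the pivot
#' @return numeric z value(s); `C = 1` gives `NA` (infinite)
#' @export
coherence_z <- function(C, V, beta = 1.15, sqrt_q = FALSE) {
  if (any(V <= 2)) stop("V must exceed 2")
  if (any(C < 0 | C > 1, na.rm = TRUE)) stop("C must lie in [0, 1]")
  q <- -(V - 2) * log(1 - C^2)
  if (sqrt_q) q <- sqrt(q)
  z <- beta * (q - beta)
  z[C == 1] <- NA_real_
  z
}

#' z-scored spike-field coherence
#'
#' Applies [coherence_z()] to a coherence estimate, taking the SFC values
#' as squared-magnitude coherence (`C = sqrt(sfc)`), with degrees of
#' freedom `V = n_spikes * n_tapers` per frequency. `dof_scale = 2` selects
#' the alternative `2 * n_spikes * n_tapers` bookkeeping.
#'
#' @param est a `coherence_estimate` from [compute_sfc()]
#' @param beta transform constant (1.15)
#' @param dof_scale multiplier on the degrees of freedom
#' @param sqrt_q see [coherence_z()]
#' @return object of class `z_coherence`: `frequencies`, `z`, `beta`, `V`
#' @export
z_transform_sfc <- function(est, beta = 1.15, dof_scale = 1, sqrt_q = FALSE) {
  V <- dof_scale * est$V
  if (any(V <= 2)) stop("degrees of freedom must exceed 2")
  z <- coherence_z(sqrt(pmin(est$sfc, 1)), V, beta = beta, sqrt_q = sqrt_q)
  structure(list(frequencies = est$frequencies, z = z, beta = beta, V = V),
            class = "z_coherence")
}

#' Trial-shuffle null for spike-field coherence
#'
#' Destroys the trial-specific spike-LFP relationship while preserving both
#' marginals: in each shuffle the trial-to-LFP assignment is permuted (each
#' trial's LFP used exactly once) and the SFC recomputed; the per-frequency
#' median over shuffles is the null estimate. Any locking that survives the
#' shuffle reflects stimulus-locked structure rather than genuine
#' trial-by-trial synchronization.
#'
#' @param spikes list of per-trial spike-time vectors
#' @param lfps list of per-trial [lfp_trace()] objects
#' @param analysis_window optional spike-selection window
#' @param cfg an [mt_config()]
#' @param n_shuffles number of random permutations (default 100)
#' @param seed integer seed
#' @param derangement if `TRUE`, reject permutations with fixed points
#' @return a `coherence_estimate` whose `sfc` is the per-frequency median
#'   across shuffles; attribute `shuffles` holds the full shuffle x
#'   frequency matrix
#' @export
shuffle_control_sfc <- function(spikes, lfps, analysis_window = NULL,
                                cfg = mt_config(), n_shuffles = 100,
                                seed = 1, derangement = FALSE) {
  n_tr <- length(spikes)
  if (n_tr < 2L || length(lfps) != n_tr) {
    stop("need >= 2 trials with matching spike and LFP lists")
  }
  set.seed(seed)
  mat <- NULL
  template <- NULL
  for (s in seq_len(n_shuffles)) {
    repeat {
      perm <- sample.int(n_tr)
      if (!derangement || !any(perm == seq_len(n_tr))) break
    }
    est <- compute_sfc(spikes, lfps[perm], analysis_window = analysis_window,
                       cfg = cfg)
    if (is.null(mat)) {
      mat <- matrix(NA_real_, n_shuffles, length(est$frequencies))
      template <- est
    }
    mat[s, ] <- est$sfc
  }
  out <- template
  out$sfc <- apply(mat, 2, median, na.rm = TRUE)
  attr(out, "shuffles") <- mat
  out
}

#' Band-average spike-field coherence
#'
#' Mean SFC over the native grid frequencies inside `[low, high]`.
#'
#' @param est a `coherence_estimate`
#' @param band a [band_definition()]
#' @return scalar mean SFC in the band
#' @export
band_average_sfc <- function(est, band) {
  idx <- est$frequencies >= band$low & est$frequencies <= band$high
  if (!any(idx)) stop(sprintf("band %s has no overlap with the frequency grid",
                              band$name))
  mean(est$sfc[idx], na.rm = TRUE)
}

#' Direct multitaper point-process/field coherence
#'
#' Independent estimator used to cross-check the STA-based SFC: over the
#' same spike-centered segments, the spike train inside each segment is
#' binned onto the segment's sample grid and the squared magnitude
#' coherence between the tapered point-process and LFP spectra is computed
#' as `|S_xy|^2 / (S_xx * S_yy)`, averaging cross- and auto-spectra over
#' segments and tapers (hybrid Hanning/Slepian configuration as in
#' [compute_sfc()]). For sparse trains (one spike per segment) this
#' coincides with the STA-based SFC up to discretization.
#'
#' @inheritParams compute_sfc
#' @return object of class `coherence_estimate` (squared-magnitude scale)
#' @export
pp_coherence <- function(spikes, lfp, analysis_window = NULL,
                         cfg = mt_config()) {
  if (!is.list(spikes) || inherits(spikes, "lfp_trace")) spikes <- list(spikes)
  if (inherits(lfp, "lfp_trace") || !is.list(lfp)) lfp <- list(as_lfp(lfp))
  half_n <- as.integer(round(cfg$window_half * cfg$rate))
  nwin <- 2L * half_n + 1L
  lseg <- list(); dseg <- list()
  for (tr in seq_along(spikes)) {
    l <- as_lfp(lfp[[tr]])
    st <- sort(as.numeric(spikes[[tr]]))
    idx <- as.integer(round((st - l$t0) * l$rate)) + 1L
    ok <- idx - half_n >= 1L & idx + half_n <= length(l$samples)
    if (!is.null(analysis_window)) {
      ok <- ok & st >= analysis_window[1] & st <= analysis_window[2]
    }
    for (i in which(ok)) {
      rng <- (idx[i] - half_n):(idx[i] + half_n)
      lseg[[length(lseg) + 1L]] <- l$samples[rng]
      d <- numeric(nwin)
      inwin <- idx[idx >= rng[1] & idx <= rng[nwin]] - rng[1] + 1L
      d[inwin] <- d[inwin] + 1
      dseg[[length(dseg) + 1L]] <- d
    }
  }
  if (length(lseg) == 0L) stop("no usable spikes for point-process coherence")
  X <- do.call(cbind, lseg)   # nwin x nseg
  D <- do.call(cbind, dseg)
  han <- hanning_taper(nwin)
  slep <- dpss_tapers(nwin, cfg$TW, cfg$K)
  coh_for <- function(tapers) {
    sxy <- 0; sxx <- 0; syy <- 0
    for (k in seq_len(ncol(tapers))) {
      Fx <- mvfft(X * tapers[, k])
      Fd <- mvfft(D * tapers[, k])
      sxy <- sxy + rowMeans(Conj(Fd) * Fx)
      sxx <- sxx + rowMeans(Mod(Fx)^2)
      syy <- syy + rowMeans(Mod(Fd)^2)
    }
    Mod(sxy)^2 / (sxx * syy)
  }
  c_han <- coh_for(matrix(han, ncol = 1))
  c_slep <- coh_for(slep)
  freqs <- (0:(nwin - 1)) * cfg$rate / nwin
  keep <- freqs <= cfg$rate / 2
  use_han <- freqs[keep] <= cfg$crossover
  sfc <- ifelse(use_han, c_han[keep], c_slep[keep])
  sfc[!is.finite(sfc)] <- NA_real_
  structure(list(frequencies = freqs[keep], sfc = sfc,
                 n_spikes = ncol(X),
                 n_tapers = ifelse(use_han, 1L, cfg$K),
                 V = ncol(X) * ifelse(use_han, 1L, cfg$K)),
            class = "coherence_estimate")
}

#' Null calibration of the z-scored SFC
#'
#' Simulates fully uncoupled data - homogeneous Poisson spikes on
#' white-noise LFP - and returns the z-scored SFC at a fixed frequency for
#' each replicate, using [compute_sfc()] and [z_transform_sfc()] end to
#' end. The replicate duration is chosen so that spike-centered windows
#' rarely overlap, the regime in which the degrees-of-freedom bookkeeping
#' applies. The sample variance of the result checks the claim that the
#' null z is a unit-variance normal variate.
#'
#' @param n_rep number of replicates
#' @param n_spikes spikes per replicate
#' @param duration replicate duration in seconds
#' @param freq frequency (Hz) at which z is read (nearest grid point)
#' @param cfg an [mt_config()]
#' @param seed integer seed
#' @param ... passed to [z_transform_sfc()]
#' @return numeric vector of z values, one per replicate
#' @export
simulate_null_z <- function(n_rep = 200, n_spikes = 1000, duration = 1000,
                            freq = 6.64, cfg = mt_config(), seed = 1, ...) {
  zs <- numeric(n_rep)
  half_n <- as.integer(round(cfg$window_half * cfg$rate))
  nsamp <- as.integer(duration * cfg$rate)
  for (r in seq_len(n_rep)) {
    set.seed(split_seed(seed, "nullz", r))
    x <- rnorm(nsamp)
    pos <- sort(sample((half_n + 1):(nsamp - half_n), n_spikes))
    st <- (pos - 1) / cfg$rate
    est <- compute_sfc(st, lfp_trace(x, rate = cfg$rate, t0 = 0), cfg = cfg)
    zc <- z_transform_sfc(est, ...)
    zs[r] <- zc$z[which.min(abs(zc$frequencies - freq))]
  }
  zs
}
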