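# Synthetic-session generator: LFP with band oscillations over 1/f
# background, von Mises phase-coupled spike trains, a Weibull observer,
# and eye traces with injected microsaccades. Every downstream analysis
# stage has known ground truth here.

#' Session configuration
#'
#' Structure and timing of a simulated discrimination session. Each block
#' holds `trials_per_block` trials: half are match trials (zero rotation)
#' and the rest are split equally over the non-zero orientations (the
#' default 96 = 48 match + 4 x 12 non-match). Trial timing is 500 ms
#' fixation, 300 ms target, 1000 ms delay (optionally jittered uniformly
#' within `delay_jitter_ms`), 300 ms test, and traces extend 100 ms past
#' test offset. All randomness derives from `seed` via [split_seed()].
#'
#' @param n_blocks number of consecutive blocks
#' @param trials_per_block trials per block
#' @param orientations rotation magnitudes in degrees; must include 0
#' @param fixation_ms,target_ms,delay_ms,test_ms epoch durations (ms)
#' @param delay_jitter_ms `NULL` for a fixed delay, or `c(min, max)` ms
#' @param lfp_rate sampling rate in samples/s
#' @param n_channels number of LFP channels
#' @param n_units number of single units
#' @param seed master integer seed
#' @return object of class `session_config`
#' @export
session_config <- function(n_blocks = 4, trials_per_block = 96,
                           orientations = c(0, 3, 5, 10, 20),
                           fixation_ms = 500, target_ms = 300,
                           delay_ms = 1000, test_ms = 300,
                           delay_jitter_ms = NULL, lfp_rate = 1000,
                           n_channels = 1, n_units = 1, seed = 1) {
  stopifnot(n_blocks >= 1, trials_per_block >= 2,
            fixation_ms > 0, target_ms > 0, delay_ms > 0, test_ms > 0,
            lfp_rate > 0, 0 %in% orientations)
  nz <- sort(orientations[orientations != 0])
  n_match <- trials_per_block / 2
  if (n_match != round(n_match) ||
      (trials_per_block - n_match) %% length(nz) != 0) {
    stop("trials_per_block must split into half match trials and equal ",
         "non-match counts per non-zero orientation")
  }
  if (!is.null(delay_jitter_ms)) {
    stopifnot(length(delay_jitter_ms) == 2, diff(delay_jitter_ms) >= 0,
              delay_jitter_ms[1] > 0)
  }
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 orientations = sort(orientations), fixation_ms = fixation_ms,
                 target_ms = target_ms, delay_ms = delay_ms,
                 test_ms = test_ms, delay_jitter_ms = delay_jitter_ms,
                 lfp_rate = lfp_rate, n_channels = n_channels,
                 n_units = n_units, seed = seed),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> %d blocks x %d trials, orientations {%s} deg, seed %d\n",
              x$n_blocks, x$trials_per_block,
              paste(x$orientations, collapse = ", "), x$seed))
  invisible(x)
}

# per-trial timing (seconds); delay may be jittered per trial
trial_timing <- function(config, trial_index) {
  delay <- config$delay_ms
  if (!is.null(config$delay_jitter_ms)) {
    set.seed(split_seed(config$seed, "delay", trial_index))
    delay <- runif(1, config$delay_jitter_ms[1], config$delay_jitter_ms[2])
  }
  fix <- config$fixation_ms / 1000
  target <- config$target_ms / 1000
  delay <- delay / 1000
  test <- config$test_ms / 1000
  list(t0 = -fix, target_on = 0, target_off = target,
       test_on = target + delay, test_off = target + delay + test,
       t_end = target + delay + test + 0.1)
}

#' Phase-coupling profile for spike generation
#'
#' Ground-truth coupling between a unit's spiking and the LFP oscillation:
#' the instantaneous rate is `base_rate * exp(kappa * cos(phi(t) -
#' preferred_phase)) / I0(kappa)` where `phi(t)` is the band-limited LFP
#' phase, so the average rate over a uniform phase cycle equals
#' `base_rate` and `kappa = 0` decouples spikes from the field entirely.
#' The LFP itself carries a sinusoidal oscillation at `osc_freq` of the
#' given amplitude over 1/f^`noise_exponent` Gaussian background noise.
#'
#' @param band `c(low, high)` Hz of the coupled oscillation band
#' @param kappa von Mises concentration, `>= 0`
#' @param preferred_phase preferred firing phase, radians
#' @param base_rate mean firing rate, spikes/s, `> 0` (0 allowed: silent)
#' @param osc_freq oscillation frequency in Hz (inside `band`)
#' @param oscillation_amplitude oscillation amplitude, arbitrary units
#' @param noise_sd standard deviation of the background noise (0 = none)
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background
#' @param coupling_epochs `NULL` for coupling throughout the trial, or a
#'   list of `c(start, end)` windows (s, relative to target onset) outside
#'   which the rate stays at `base_rate`
#' @return object of class `coupling_profile`
#' @export
coupling_profile <- function(band = c(4, 8), kappa = 0, preferred_phase = 0,
                             base_rate = 10, osc_freq = mean(band),
                             oscillation_amplitude = 1, noise_sd = 1,
                             noise_exponent = 1, coupling_epochs = NULL) {
  if (!(band[1] < band[2])) stop("invalid band range: low >= high")
  if (kappa < 0) stop("kappa must be >= 0")
  if (base_rate < 0) stop("base_rate must be >= 0")
  structure(list(band = band, kappa = kappa,
                 preferred_phase = preferred_phase, base_rate = base_rate,
                 osc_freq = osc_freq,
                 oscillation_amplitude = oscillation_amplitude,
                 noise_sd = noise_sd, noise_exponent = noise_exponent,
                 coupling_epochs = coupling_epochs),
            class = "coupling_profile")
}

#' Weibull observer model
#'
#' Per-block psychometric parameters of the simulated observer: response
#' accuracy at rotation `dtheta` follows
#' `P = 1 - (1 - FA) exp(-(dtheta/a)^b)`, so accuracy on match trials is
#' `1 - FA`. Scalars are recycled across blocks.
#'
#' @param FA false-alarm probability per block, in [0, 1)
#' @param a offset term per block, degrees > 0
#' @param b slope term per block, > 0
#' @param n_blocks number of blocks the parameters are expanded to
#' @return object of class `observer_model` with per-block vectors
#' @export
observer_model <- function(FA = 0.1, a = 8, b = 2, n_blocks = 4) {
  if (any(FA < 0 | FA >= 1)) stop("FA must be in [0, 1)")
  if (any(a <= 0) || any(b <= 0)) stop("a and b must be positive")
  structure(list(FA = rep_len(FA, n_blocks), a = rep_len(a, n_blocks),
                 b = rep_len(b, n_blocks), n_blocks = n_blocks),
            class = "observer_model")
}

# 1/f^alpha Gaussian noise of length n, unit SD, deterministic given the
# current RNG state
pink_noise <- function(n, alpha = 1) {
  nf <- n %/% 2
  amp <- c(0, (1:nf)^(-alpha / 2), if (n %% 2 == 0) NULL else NULL)
  # build full Hermitian spectrum
  ph <- runif(nf, 0, 2 * pi)
  pos <- amp[-1] * exp(1i * ph)
  if (n %% 2 == 0) {
    spec <- c(0, pos[-nf], Re(pos[nf]), Conj(rev(pos[-nf])))
  } else {
    spec <- c(0, pos, Conj(rev(pos)))
  }
  x <- Re(fft(spec, inverse = TRUE))
  x / sd(x)
}

#' Generate one trial's LFP trace
#'
#' Band oscillation (`oscillation_amplitude * cos(2 pi f t + phi0)` with a
#' per-trial random starting phase) plus 1/f^alpha Gaussian background,
#' spanning fixation onset through 100 ms after test offset. Deterministic
#' given the config seed, trial index and channel. The oscillator's exact
#' phase series is attached as attribute `osc_phase` (ground truth for
#' phase-recovery tests).
#'
#' @param config a [session_config()]
#' @param profile a [coupling_profile()]
#' @param trial_index trial number within the session
#' @param channel LFP channel index
#' @return an [lfp_trace()]
#' @export
generate_lfp <- function(config, profile, trial_index, channel = 1) {
  stopifnot(inherits(config, "session_config"),
            inherits(profile, "coupling_profile"))
  tm <- trial_timing(config, trial_index)
  n <- as.integer(round((tm$t_end - tm$t0) * config$lfp_rate)) + 1L
  t <- tm$t0 + (0:(n - 1)) / config$lfp_rate
  set.seed(split_seed(config$seed, paste0("lfp_ch", channel), trial_index))
  phi0 <- runif(1, 0, 2 * pi)
  osc_phase <- wrap_angle(2 * pi * profile$osc_freq * t + phi0)
  x <- profile$oscillation_amplitude * cos(osc_phase)
  if (profile$noise_sd > 0) {
    x <- x + profile$noise_sd * pink_noise(n, profile$noise_exponent)
  }
  out <- lfp_trace(x, rate = config$lfp_rate, t0 = tm$t0)
  attr(out, "osc_phase") <- osc_phase
  out
}

# band-limited Hilbert phase used by the generator (zero-phase Butterworth;
# the analysis module independently uses the equiripple FIR path)
generator_phase <- function(lfp, band) {
  ny <- lfp$rate / 2
  bf <- signal::butter(4, pmin(band, ny * 0.99) / ny, type = "pass")
  instantaneous_phase(signal::filtfilt(bf, lfp$samples))
}

#' Generate a phase-coupled spike train
#'
#' Inhomogeneous Bernoulli process on the LFP sample grid with rate
#' `base_rate * exp(kappa cos(phi(t) - preferred_phase)) / I0(kappa)`,
#' where `phi(t)` is the band-filtered Hilbert phase of the supplied LFP.
#' Averaged over a uniform phase, the expected rate equals `base_rate`.
#' Outside any `coupling_epochs` of the profile the rate is `base_rate`.
#'
#' @param lfp an [lfp_trace()] covering the trial
#' @param profile a [coupling_profile()] (`kappa >= 0` enforced)
#' @param seed integer seed (pass [split_seed()] output for session use)
#' @return numeric vector of spike times (s, same time base as the LFP)
#' @export
generate_spikes <- function(lfp, profile, seed = 1) {
  stopifnot(inherits(profile, "coupling_profile"))
  if (profile$kappa < 0) stop("kappa must be >= 0")
  if (profile$base_rate == 0) return(numeric(0))
  t <- lfp_time(lfp)
  dt <- 1 / lfp$rate
  if (profile$kappa > 0) {
    phi <- generator_phase(lfp, profile$band)
    # exp(kappa (cos - 1)) / (I0(kappa) e^-kappa) avoids overflow at large kappa
    mod <- exp(profile$kappa * (cos(phi - profile$preferred_phase) - 1)) /
      besselI(profile$kappa, 0, expon.scaled = TRUE)
    if (!is.null(profile$coupling_epochs)) {
      inside <- rep(FALSE, length(t))
      for (ep in profile$coupling_epochs) {
        inside <- inside | (t >= ep[1] & t <= ep[2])
      }
      mod[!inside] <- 1
    }
    r <- profile$base_rate * mod
  } else {
    r <- rep(profile$base_rate, length(t))
  }
  set.seed(seed)
  p <- pmin(r * dt, 1)
  t[rbinom(length(p), 1L, p) == 1L]
}

# deterministic trial table (block, dtheta, is_match) for a config
session_trial_table <- function(config) {
  nz <- config$orientations[config$orientations != 0]
  per_nz <- (config$trials_per_block / 2) / length(nz)
  rows <- list()
  for (b in seq_len(config$n_blocks)) {
    dthetas <- c(rep(0, config$trials_per_block / 2), rep(nz, each = per_nz))
    set.seed(split_seed(config$seed, "trialorder", b))
    dthetas <- sample(dthetas)
    rows[[b]] <- data.frame(block = b, dtheta = dthetas)
  }
  out <- do.call(rbind, rows)
  out$trial <- seq_len(nrow(out))
  out$is_match <- out$dtheta == 0
  out[, c("trial", "block", "dtheta", "is_match")]
}

#' Generate one trial's behavioral outcome
#'
#' Draws the correct/incorrect flag as a Bernoulli with success probability
#' given by the block's Weibull observer (so the long-run error rate on
#' match trials equals that block's `FA`). The trial's rotation comes from
#' the session's deterministic block composition unless `dtheta` is given.
#'
#' @param config a [session_config()]
#' @param observer an [observer_model()]
#' @param trial_index trial number within the session
#' @param dtheta optional rotation override in degrees
#' @return one-row data.frame: `trial`, `block`, `dtheta`, `is_match`,
#'   `correct`, `response` (`"release"` or `"hold"`)
#' @export
generate_behavior <- function(config, observer, trial_index, dtheta = NULL) {
  stopifnot(inherits(observer, "observer_model"))
  n_total <- config$n_blocks * config$trials_per_block
  if (trial_index > n_total) stop("trial_index beyond the session")
  if (is.null(dtheta)) {
    tab <- session_trial_table(config)
    row <- tab[trial_index, ]
  } else {
    row <- data.frame(trial = trial_index,
                      block = ceiling(trial_index / config$trials_per_block),
                      dtheta = dtheta, is_match = dtheta == 0)
  }
  b <- row$block
  p_correct <- if (row$dtheta == 0) 1 - observer$FA[b] else
    weibull_p(row$dtheta, observer$FA[b], observer$a[b], observer$b[b])
  set.seed(split_seed(config$seed, "behavior", trial_index))
  correct <- runif(1) < p_correct
  response <- if (row$is_match) {
    if (correct) "release" else "hold"
  } else {
    if (correct) "hold" else "release"
  }
  data.frame(trial = row$trial, block = row$block, dtheta = row$dtheta,
             is_match = row$is_match, correct = correct, response = response)
}

#' Generate an eye-position trace with injected microsaccades
#'
#' Slow fixational drift (low-passed Gaussian noise, about 0.02 deg SD)
#' plus step-like microsaccades: events arrive as a Poisson process at
#' `microsaccade_rate`, each realized as a linear 10-ms displacement of
#' random direction and an amplitude drawn from `amplitudes` (a `c(min,
#' max)` range, or a discrete set if more values are given). The injected
#' event list is returned as ground truth.
#'
#' @param config a [session_config()]
#' @param microsaccade_rate events per second, `>= 0`
#' @param amplitudes event amplitudes in degrees, all `>= 0`
#' @param trial_index trial number (seeds the trace)
#' @return object of class `eye_trace`: `x`, `y` (degrees at `lfp_rate`),
#'   `rate`, `t0`, and `events` (data.frame `time`, `amplitude`,
#'   `direction`)
#' @export
generate_eye_trace <- function(config, microsaccade_rate = 0.2,
                               amplitudes = c(0.05, 0.2), trial_index = 1) {
  if (microsaccade_rate < 0) stop("microsaccade_rate must be >= 0")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  tm <- trial_timing(config, trial_index)
  rate <- config$lfp_rate
  n <- as.integer(round((tm$t_end - tm$t0) * rate)) + 1L
  set.seed(split_seed(config$seed, "eye", trial_index))
  bf <- signal::butter(2, 2 / (rate / 2), type = "low")
  drift <- function() {
    d <- signal::filtfilt(bf, rnorm(n))
    0.02 * d / max(sd(d), 1e-12)
  }
  x <- drift(); y <- drift()
  dur <- (n - 1) / rate
  n_ev <- rpois(1, microsaccade_rate * dur)
  step_n <- as.integer(round(0.010 * rate))
  events <- data.frame(time = numeric(0), amplitude = numeric(0),
                       direction = numeric(0))
  if (n_ev > 0) {
    times <- sort(runif(n_ev, 0.02, dur - 0.02))
    for (ev in seq_len(n_ev)) {
      amp <- if (length(amplitudes) == 2) {
        runif(1, amplitudes[1], amplitudes[2])
      } else sample(amplitudes, 1)
      dir <- runif(1, 0, 2 * pi)
      i0 <- as.integer(round(times[ev] * rate)) + 1L
      ramp <- seq(0, 1, length.out = step_n + 1)
      seg <- i0:min(i0 + step_n, n)
      x[seg] <- x[seg] + amp * cos(dir) * ramp[seq_along(seg)]
      if (i0 + step_n < n) x[(i0 + step_n + 1):n] <- x[(i0 + step_n + 1):n] + amp * cos(dir)
      y[seg] <- y[seg] + amp * sin(dir) * ramp[seq_along(seg)]
      if (i0 + step_n < n) y[(i0 + step_n + 1):n] <- y[(i0 + step_n + 1):n] + amp * sin(dir)
      events <- rbind(events, data.frame(time = times[ev], amplitude = amp,
                                         direction = dir))
    }
  }
  structure(list(x = x, y = y, rate = rate, t0 = tm$t0, events = events),
            class = "eye_trace")
}

#' Generate a complete synthetic session
#'
#' Assembles all trials of a session: trial table with behavioral outcomes,
#' per-channel LFP traces, per-unit phase-coupled spike trains (unit `u`
#' couples to channel `min(u, n_channels)`), and eye traces. Block-wise
#' coupling and observer ground truth are embedded under `$ground_truth`.
#' Fully reproducible from the config seed.
#'
#' @param config a [session_config()]
#' @param profiles a [coupling_profile()], or a list of one per block
#' @param observer an [observer_model()] with matching `n_blocks`
#' @param microsaccade_rate,amplitudes passed to [generate_eye_trace()]
#' @return object of class `sf_session`: `config`, `trials` (data.frame),
#'   `lfp` (list channel -> list of trial traces), `spikes` (list unit ->
#'   list of trial spike vectors), `eye` (list of `eye_trace`),
#'   `ground_truth`
#' @export
generate_session <- function(config, profiles, observer,
                             microsaccade_rate = 0.2,
                             amplitudes = c(0.05, 0.2)) {
  stopifnot(inherits(config, "session_config"))
  if (inherits(profiles, "coupling_profile")) {
    profiles <- rep(list(profiles), config$n_blocks)
  }
  if (length(profiles) != config$n_blocks) {
    stop("need one coupling profile per block")
  }
  if (observer$n_blocks != config$n_blocks) {
    stop("observer block count does not match the config")
  }
  trials <- session_trial_table(config)
  n_tr <- nrow(trials)
  beh <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
    generate_behavior(config, observer, i, dtheta = trials$dtheta[i])
  }))
  trials$correct <- beh$correct
  trials$response <- beh$response
  timing <- lapply(seq_len(n_tr), function(i) trial_timing(config, i))
  trials$test_on <- vapply(timing, `[[`, numeric(1), "test_on")
  trials$test_off <- vapply(timing, `[[`, numeric(1), "test_off")
  lfp <- vector("list", config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    lfp[[ch]] <- lapply(seq_len(n_tr), function(i) {
      generate_lfp(config, profiles[[trials$block[i]]], i, channel = ch)
    })
  }
  spikes <- vector("list", config$n_units)
  for (u in seq_len(config$n_units)) {
    ch <- min(u, config$n_channels)
    spikes[[u]] <- lapply(seq_len(n_tr), function(i) {
      generate_spikes(lfp[[ch]][[i]], profiles[[trials$block[i]]],
                      seed = split_seed(config$seed, paste0("spk_u", u), i))
    })
  }
  eye <- lapply(seq_len(n_tr), function(i) {
    generate_eye_trace(config, microsaccade_rate, amplitudes, i)
  })
  # electrode geometry for near/far pair classification (mm along the grid)
  set.seed(split_seed(config$seed, "geometry", 0))
  channel_pos <- sort(runif(config$n_channels, 0, 4))
  unit_pos <- channel_pos[pmin(seq_len(config$n_units), config$n_channels)]
  structure(list(config = config, trials = trials, lfp = lfp,
                 spikes = spikes, eye = eye,
                 channel_positions = channel_pos, unit_positions = unit_pos,
                 ground_truth = list(profiles = profiles,
                                     observer = observer)),
            class = "sf_session")
}

#' @export
print.sf_session <- function(x, ...) {
  cat(sprintf("<sf_session> %d trials in %d blocks, %d channel(s), %d unit(s)\n",
              nrow(x$trials), x$config$n_blocks, x$config$n_channels,
              x$config$n_units))
  invisible(x)
}

#' Session presets for the three learning regimes
#'
#' Ready-made generator settings emulating the three session types:
#' `"novel"` (theta coupling stepping up after block 1 while the observer's
#' threshold steps down - the learning regime), `"familiar"` (flat high
#' coupling, low flat threshold), and `"no_learning"` (flat low coupling,
#' high flat threshold). Coupling is confined to the stimulus epochs
#' (0-300 ms after target onset and after test onset), so delay-period
#' coherence carries no block effect.
#'
#' @param condition preset name
#' @param seed master session seed
#' @param base_rate mean firing rate in spikes/s
#' @param n_channels,n_units forwarded to [session_config()]
#' @return list with `config`, `profiles`, `observer` ready for
#'   [generate_session()]
#' @export
session_preset <- function(condition = c("novel", "familiar", "no_learning"),
                           seed = 1, base_rate = 20, n_channels = 1,
                           n_units = 1) {
  condition <- match.arg(condition)
  config <- session_config(seed = seed, n_channels = n_channels,
                           n_units = n_units)
  stim_epochs <- list(c(0, 0.3), c(1.3, 1.6))
  # kappa 0.5 -> 0.6 steps the generative phase-locking (I1/I0 ratio squared)
  # by ~40%, the order of the median theta SFC increase seen during learning
  kappas <- switch(condition,
                   novel = c(0.5, 0.6, 0.6, 0.6),
                   familiar = rep(0.6, 4),
                   no_learning = rep(0.5, 4))
  a_blocks <- switch(condition,
                     novel = c(17, 7, 5, 4.2),
                     familiar = rep(4.2, 4),
                     no_learning = rep(17, 4))
  profiles <- lapply(kappas, function(k) {
    coupling_profile(band = c(4, 8), kappa = k, preferred_phase = pi / 3,
                     base_rate = base_rate, osc_freq = 6,
                     oscillation_amplitude = 1, noise_sd = 1,
                     noise_exponent = 1, coupling_epochs = stim_epochs)
  })
  observer <- observer_model(FA = 0.1, a = a_blocks, b = 1.3, n_blocks = 4)
  list(config = config, profiles = profiles, observer = observer,
       condition = condition)
}
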