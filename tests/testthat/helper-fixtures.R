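# Shared fixtures, all built in code at test time.

# pure sinusoid as an lfp_trace
sinusoid_lfp <- function(freq = 6, dur = 10, rate = 1000, amp = 1,
                         phase = 0, t0 = 0) {
  t <- (0:(dur * rate - 1)) / rate
  lfp_trace(amp * cos(2 * pi * freq * t + phase), rate = rate, t0 = t0)
}

# spike times at successive peaks of a cosine of frequency f
peak_spikes <- function(freq = 6, n = 200, from = 0.2) {
  k <- ceiling(from * freq)
  (k:(k + n - 1)) / freq
}

# enforce a minimum gap so every spike-centered window holds one spike
enforce_gap <- function(st, gap = 0.31) {
  keep <- numeric(0)
  last <- -Inf
  for (s in st) {
    if (s - last >= gap) {
      keep <- c(keep, s)
      last <- s
    }
  }
  keep
}

# von Mises angles by rejection sampling
rvonmises <- function(n, mu = 0, kappa = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, -pi, pi)
    acc <- runif(2 * n) < exp(kappa * (cos(x - mu) - 1))
    out <- c(out, x[acc])
  }
  out[seq_len(n)]
}

# simulate behavioral trials of a Weibull observer (direct Bernoulli draw;
# independent of the generator's session machinery)
sim_observer_trials <- function(n_per_level, FA = 0.1, a = 8, b = 2,
                                dthetas = c(0, 3, 5, 10, 20), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(dthetas, function(d) {
    p <- if (d == 0) 1 - FA else weibull_p(d, FA, a, b)
    data.frame(dtheta = d, correct = rbinom(n_per_level, 1, p) == 1)
  }))
}

# long single-trial session config for coupling fixtures
long_trial_config <- function(delay_ms = 18000, seed = 1) {
  session_config(n_blocks = 1, trials_per_block = 2, orientations = c(0, 5),
                 delay_ms = delay_ms, seed = seed)
}

# memoized full sessions + results shared across test files
.fixtures <- new.env(parent = emptyenv())

cached_session <- function(condition, seed = 11, n_channels = 1, n_units = 1) {
  key <- paste(condition, seed, n_channels, n_units, sep = "_")
  if (is.null(.fixtures[[key]])) {
    ps <- session_preset(condition, seed = seed, n_channels = n_channels,
                         n_units = n_units)
    .fixtures[[key]] <- generate_session(ps$config, ps$profiles, ps$observer)
  }
  .fixtures[[key]]
}

cached_result <- function(condition, seed = 11, n_channels = 1, n_units = 1,
                          run_seed = 5) {
  key <- paste("res", condition, seed, n_channels, n_units, run_seed,
               sep = "_")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- run_session(
      cached_session(condition, seed, n_channels, n_units), seed = run_seed)
  }
  .fixtures[[key]]
}
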