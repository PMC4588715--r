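# Band filtering, instantaneous phase, spike-phase distributions and
# circular statistics.

test_that("theta equiripple filter meets its passband and stopband spec", {
  spec <- band_filter_spec("theta")
  mid <- 5000:15000
  s6 <- band_filter(sinusoid_lfp(6, dur = 20), spec)
  expect_equal(max(abs(s6$samples[mid])), 1, tolerance = 0.12)  # 1 dB ripple
  s20 <- band_filter(sinusoid_lfp(20, dur = 20), spec)
  atten <- 20 * log10(max(abs(s20$samples[mid])))
  expect_lt(atten, -40)
  # 6 + 40 Hz mixture: output is the 6 Hz component (spectral oracle)
  mix <- lfp_trace(sinusoid_lfp(6, dur = 20)$samples +
                     sinusoid_lfp(40, dur = 20)$samples)
  fm <- band_filter(mix, spec)
  expect_gt(cor(fm$samples[mid], sinusoid_lfp(6, dur = 20)$samples[mid]),
            0.999)
  expect_error(band_filter_spec(stop_low = 5, pass_low = 4, pass_high = 8,
                                stop_high = 9), "edges")
})

test_that("instantaneous phase tracks the analytic signal", {
  rate <- 1000
  t <- (0:9999) / rate
  ph_cos <- instantaneous_phase(cos(2 * pi * 6 * t))
  expect_lt(abs(ph_cos[1]), 0.05)
  ph_sin <- instantaneous_phase(sin(2 * pi * 6 * t))
  expect_lt(abs(ph_sin[1] + pi / 2), 0.05)
  # unwrapped phase advances at 2 pi f rad/s (linear fit oracle)
  mid <- 2000:8000
  unw <- spikefield:::wrap_angle(ph_cos)
  steps <- diff(ph_cos[mid])
  steps <- steps[abs(steps) < pi]
  slope <- mean(steps) * rate
  expect_equal(slope, 2 * pi * 6, tolerance = 0.01)
  expect_error(instantaneous_phase(numeric(100)), "zero")
})

test_that("spike phases are read at spike times within the window", {
  lfp <- sinusoid_lfp(6, dur = 20)
  ph <- instantaneous_phase(lfp$samples)
  st <- peak_spikes(6, 60)
  pd <- spike_phases(st, ph, window = c(0, 20), rate = 1000, t0 = 0)
  expect_equal(pd$n, 60)
  expect_lt(max(abs(pd$angles)), 0.1)  # peaks of a cosine sit at phase 0
  none <- spike_phases(st, ph, window = c(30, 40), rate = 1000, t0 = 0)
  expect_equal(none$n, 0)
  # generator ground truth: strong coupling at preferred phase pi/2
  cfg <- long_trial_config(delay_ms = 18000, seed = 21)
  prof <- coupling_profile(kappa = 4, preferred_phase = pi / 2,
                           base_rate = 12, noise_sd = 0)
  lfpg <- generate_lfp(cfg, prof, 1)
  stg <- generate_spikes(lfpg, prof, seed = 8)
  filt <- band_filter(lfpg, band_filter_spec("theta"))
  pdg <- spike_phases(stg, instantaneous_phase(filt), window = c(1, 17),
                      rate = 1000, t0 = lfpg$t0)
  expect_gt(pdg$n, 100)
  expect_lt(abs(spikefield:::circ_dist(spikefield:::circ_mean(pdg$angles),
                                       pi / 2)), 0.2)
})

test_that("theta phases from the filter agree with the oscillator truth", {
  cfg <- long_trial_config(delay_ms = 18000, seed = 22)
  prof <- coupling_profile(kappa = 2, base_rate = 15, noise_sd = 0)
  lfp <- generate_lfp(cfg, prof, 1)
  st <- generate_spikes(lfp, prof, seed = 7)
  filt <- band_filter(lfp, band_filter_spec("theta"))
  pd <- spike_phases(st, instantaneous_phase(filt), window = c(1, 17),
                     rate = 1000, t0 = lfp$t0)
  truth <- attr(lfp, "osc_phase")
  sidx <- round((st[st >= 1 & st <= 17] - lfp$t0) * 1000) + 1
  tru <- truth[sidx]
  circ_corr <- function(a, b) {
    sa <- sin(a - spikefield:::circ_mean(a))
    sb <- sin(b - spikefield:::circ_mean(b))
    sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
  }
  expect_gt(circ_corr(pd$angles, tru), 0.95)
})

test_that("Rayleigh Z obeys its closed-form limits and null expectation", {
  expect_equal(rayleigh_z(rep(1.3, 25)), 25)       # identical angles: Z = n
  expect_lt(rayleigh_z(c(0.4, 0.4 + pi)), 1e-20)   # antipodal pair cancels
  set.seed(51)
  zs <- replicate(400, rayleigh_z(runif(100, -pi, pi)))
  expect_equal(mean(zs), 1, tolerance = 0.15)      # E[Z] ~ 1 under uniformity
  expect_error(rayleigh_z(numeric(0)), "angle")
})

test_that("uniformity tests detect locking and hold their size", {
  set.seed(52)
  locked <- rvonmises(200, mu = 1, kappa = 2)
  ut <- uniformity_tests(locked)
  expect_true(ut$computable)
  expect_lt(ut$rayleigh$p.value, 0.001)
  expect_lt(ut$omnibus$p.value, 0.01)
  expect_true(ut$locked)
  # all-identical angles: p collapses to the floating floor
  ident <- uniformity_tests(rep(0.7, 50))
  expect_lt(ident$rayleigh$p.value, 1e-12)
  # type-I calibration near the nominal 5% level
  set.seed(53)
  rej <- replicate(400, {
    a <- runif(200, -pi, pi)
    c(rayleigh_test(a)$p.value < 0.05, omnibus_test(a)$p.value < 0.05)
  })
  expect_gt(mean(rej[1, ]), 0.02); expect_lt(mean(rej[1, ]), 0.09)
  expect_gt(mean(rej[2, ]), 0.01); expect_lt(mean(rej[2, ]), 0.09)
  # too few spikes: flagged not computable
  expect_false(uniformity_tests(c(0.1, 0.2))$computable)
})

test_that("rotation leaves Z and uniformity p-values unchanged", {
  set.seed(54)
  a <- rvonmises(120, mu = 0.5, kappa = 1)
  for (rot in c(0.8, -2.1)) {
    b <- spikefield:::wrap_angle(a + rot)
    expect_equal(rayleigh_z(b), rayleigh_z(a), tolerance = 1e-9)
    expect_equal(rayleigh_test(b)$p.value, rayleigh_test(a)$p.value,
                 tolerance = 1e-9)
    expect_equal(omnibus_test(b)$p.value, omnibus_test(a)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Kuiper test is rotation invariant and detects phase shifts", {
  set.seed(55)
  a <- rvonmises(100, mu = 0, kappa = 1.5)
  b <- rvonmises(100, mu = 0, kappa = 1.5)
  same <- kuiper_test(a, b)
  expect_gt(same$p.value, 0.05)
  shifted <- kuiper_test(a, spikefield:::wrap_angle(b + pi))
  expect_lt(shifted$p.value, 0.001)
  rot <- 1.234
  k1 <- kuiper_test(a, b)
  k2 <- kuiper_test(spikefield:::wrap_angle(a + rot),
                    spikefield:::wrap_angle(b + rot))
  expect_equal(k2$V, k1$V, tolerance = 1e-9)
})

test_that("the common-median test separates opposed preferred phases", {
  set.seed(56)
  a <- rvonmises(150, mu = 0.3, kappa = 1.5)
  dup <- circ_cmtest(list(a, a))
  expect_gt(dup$p.value, 0.99)
  opp <- circ_cmtest(list(rvonmises(150, mu = 0, kappa = 1.5),
                          rvonmises(150, mu = pi, kappa = 1.5)))
  expect_lt(opp$p.value, 0.001)
  rep4 <- compare_phase_distributions(list(a, a, a, a))
  expect_gt(rep4$cmtest$p.value, 0.9)
  expect_equal(nrow(rep4$pairwise), 6)
  expect_error(compare_phase_distributions(list(a)), "non-empty")
})

test_that("trial-shuffled Rayleigh Z separates coupling from stimulus locking", {
  # enough trials that permutation fixed points (which preserve coupling)
  # are a small fraction of the shuffled pool
  n_tr <- 20
  cfg <- session_config(n_blocks = 1, trials_per_block = n_tr,
                        orientations = c(0, 5), delay_ms = 3000, seed = 61)
  prof <- coupling_profile(kappa = 2, base_rate = 15, noise_sd = 0.4)
  lfps <- lapply(1:n_tr, function(i) generate_lfp(cfg, prof, i))
  phases <- lapply(lfps, function(l) {
    lfp_trace(instantaneous_phase(band_filter(l, band_filter_spec("theta"))),
              rate = l$rate, t0 = l$t0)
  })
  win <- c(0, 1.5)
  spikes <- lapply(1:n_tr, function(i) generate_spikes(lfps[[i]], prof,
                                                       seed = 500 + i))
  res <- shuffled_phase_z(spikes, phases, window = win, n_shuffles = 50,
                          seed = 2)
  expect_gt(res$z_observed, 10 * res$z_shuffled)
  # uncoupled spikes: shuffled and observed Z are both near 1
  prof0 <- coupling_profile(kappa = 0, base_rate = 15, noise_sd = 0.4)
  sp0 <- lapply(1:n_tr, function(i) generate_spikes(lfps[[i]], prof0,
                                                    seed = 600 + i))
  res0 <- shuffled_phase_z(sp0, phases, window = win, n_shuffles = 50,
                           seed = 3)
  expect_lt(res0$z_observed, 6)
  expect_lt(res0$z_shuffled, 6)
  expect_error(shuffled_phase_z(spikes[1], phases[1]), "trials")
})
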