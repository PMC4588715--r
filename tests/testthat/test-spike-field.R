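# STA, spike-field coherence, subsampling, z-transform, shuffle controls.

test_that("STA reproduces construction-level expectations", {
  # constant LFP: STA is that constant
  const <- lfp_trace(rep(2.5, 5000), rate = 1000)
  sta <- compute_sta(seq(0.5, 4.5, by = 0.1), const)
  expect_true(all(abs(sta$trace$samples - 2.5) < 1e-12))
  expect_equal(length(sta$trace$samples), 301)
  # spikes at cosine peaks: STA is the sinusoid segment with its peak at lag 0
  lfp <- sinusoid_lfp(6, dur = 40)
  sta2 <- compute_sta(peak_spikes(6, 100), lfp)
  expect_equal(sta2$n_spikes, 100)
  expect_equal(which.max(sta2$trace$samples), 151, tolerance = 1)
  expect_equal(max(sta2$trace$samples), 1, tolerance = 0.01)
  # random spikes on noise: amplitude shrinks like 1/sqrt(n)
  set.seed(41)
  noise <- lfp_trace(rnorm(4e5), rate = 1000)
  amp_for <- function(n) {
    st <- sort(runif(n, 1, 398))
    sd(compute_sta(st, noise)$trace$samples)
  }
  ratio <- amp_for(50) / amp_for(800)
  expect_gt(ratio, 4 / 1.6)
  expect_lt(ratio, 4 * 1.6)
  # zero usable spikes: empty result distinct from numeric zero
  empty <- compute_sta(numeric(0), lfp)
  expect_identical(empty$n_spikes, 0L)
  expect_null(empty$trace)
})

test_that("SFC reaches 1 for perfect locking and stays near 0 without coupling", {
  lfp <- sinusoid_lfp(6, dur = 40)
  est <- compute_sfc(peak_spikes(6, 200), lfp)
  i6 <- which.min(abs(est$frequencies - 6))
  expect_gte(est$sfc[i6], 0.99)
  set.seed(42)
  noise <- lfp_trace(rnorm(4e5), rate = 1000)
  sfc_null <- function(n) {
    st <- sort(sample(200:399800, n)) / 1000
    est <- compute_sfc(st, noise)
    mean(est$sfc[est$frequencies > 0 & est$frequencies <= 30])
  }
  lo <- sfc_null(100)
  hi <- sfc_null(1000)
  expect_lt(lo, 0.05)
  expect_lt(hi, lo)  # null level decreases with spike count
})

test_that("SFC is exactly scale invariant and bounded in [0, 1]", {
  set.seed(43)
  for (alpha in c(0.1, 10)) {
    lfp <- lfp_trace(rnorm(20000) + sinusoid_lfp(6, dur = 20)$samples)
    st <- sort(runif(150, 0.2, 19.8))
    a <- compute_sfc(st, lfp)
    b <- compute_sfc(st, lfp_trace(alpha * lfp$samples, rate = 1000))
    ok <- is.finite(a$sfc)
    expect_lt(max(abs(a$sfc[ok] - b$sfc[ok])), 1e-12)
  }
  # bounds on many random fixtures (mixed oscillation/noise/spike regimes)
  set.seed(44)
  for (r in 1:300) {
    n <- sample(c(5, 20, 60), 1)
    x <- rnorm(4000) * runif(1, 0.1, 5) +
      runif(1, 0, 2) * cos(2 * pi * runif(1, 2, 90) * (0:3999) / 1000)
    st <- sort(runif(n, 0.2, 3.8))
    est <- compute_sfc(st, lfp_trace(x, rate = 1000))
    ok <- is.finite(est$sfc)
    expect_true(all(est$sfc[ok] >= 0 & est$sfc[ok] <= 1 + 1e-12))
  }
})

test_that("STA-based SFC matches direct point-process coherence", {
  # sparse coupled fixtures: the two estimators coincide analytically at
  # single-taper frequencies when each window holds one spike
  worst <- 0
  for (fx in 1:20) {
    cfg <- session_config(n_blocks = 1, trials_per_block = 2,
                          orientations = c(0, 5), delay_ms = 38000,
                          seed = 200 + fx)
    prof <- coupling_profile(kappa = 1.5, base_rate = 6, noise_sd = 0.6)
    lfp <- generate_lfp(cfg, prof, 1)
    st <- enforce_gap(generate_spikes(lfp, prof, seed = fx))
    sta_sfc <- compute_sfc(st, lfp)
    direct <- pp_coherence(st, lfp)
    sel <- sta_sfc$frequencies > 0 & sta_sfc$frequencies <= 30
    rms <- sqrt(mean((sta_sfc$sfc[sel] - direct$sfc[sel])^2))
    worst <- max(worst, rms)
  }
  expect_lt(worst, 0.02)
})

test_that("SFC increases with coupling strength at fixed rate", {
  cfg <- long_trial_config(delay_ms = 28000, seed = 9)
  vals <- vapply(c(0, 0.5, 1, 2), function(k) {
    prof <- coupling_profile(kappa = k, base_rate = 20, noise_sd = 0.6)
    lfp <- generate_lfp(cfg, prof, 1)
    st <- generate_spikes(lfp, prof, seed = 5)
    expect_gte(length(st), 500)
    band_average_sfc(compute_sfc(st, lfp), sfc_bands()$theta)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("SFC is rate-robust once spike counts are equalized", {
  cfg <- long_trial_config(delay_ms = 28000, seed = 9)
  prof_lo <- coupling_profile(kappa = 1, base_rate = 10, noise_sd = 0.6)
  prof_hi <- coupling_profile(kappa = 1, base_rate = 20, noise_sd = 0.6)
  lfp <- generate_lfp(cfg, prof_lo, 1)
  s_lo <- generate_spikes(lfp, prof_lo, seed = 2)
  s_hi <- generate_spikes(lfp, prof_hi, seed = 3)
  eq <- subsample_spikes(list(lo = s_lo, hi = s_hi), seed = 4)
  expect_length(eq$lo, min(length(s_lo), length(s_hi)))
  expect_length(eq$hi, min(length(s_lo), length(s_hi)))
  th <- vapply(eq, function(s) {
    band_average_sfc(compute_sfc(s, lfp), sfc_bands()$theta)
  }, numeric(1))
  # doubling the rate then equalizing changes band SFC only by Monte-Carlo error
  expect_lt(abs(th[1] - th[2]) / th[1], 0.35)
})

test_that("sliding SFC has the expected window grid and epoch confinement", {
  # arithmetic: a span of -0.1 .. 1.7 s gives floor((1.8 - 0.3)/0.01) + 1 = 151
  lfp <- lfp_trace(rnorm(1801), rate = 1000, t0 = -0.1)
  st <- sort(runif(40, 0, 1.5))
  sl <- sliding_sfc(st, lfp)
  expect_length(sl$times, 151)
  expect_equal(diff(sl$times)[1], 0.01, tolerance = 1e-9)
  # coupling confined to the stimulus epochs shows up only there
  sess <- cached_session("novel")
  idx <- which(sess$trials$block == 4)[1:24]
  sl2 <- sliding_sfc(sess$spikes[[1]][idx], sess$lfp[[1]][idx])
  i_theta <- which.min(abs(sl2$frequencies - 6.64))
  stim <- sl2$map[sl2$times > 0.05 & sl2$times < 0.25, i_theta]
  delay <- sl2$map[sl2$times > 0.5 & sl2$times < 1.1, i_theta]
  expect_gt(mean(stim, na.rm = TRUE), 3 * mean(delay, na.rm = TRUE))
})

test_that("spike-count equalization follows the minimum rule", {
  set.seed(45)
  sets <- lapply(c(100, 80, 90, 85), function(n) sort(runif(n, 0, 10)))
  eq <- subsample_spikes(sets, seed = 1)
  expect_equal(lengths(eq), rep(80L, 4), ignore_attr = TRUE)
  expect_true(all(eq[[1]] %in% sets[[1]]))     # without replacement subsets
  eq2 <- subsample_spikes(sets, seed = 2)
  expect_false(identical(eq[[1]], eq2[[1]]))   # seed controls the draw
  expect_equal(lengths(eq2), lengths(eq))
  # per-trial structure is preserved
  nested <- list(b1 = list(1:3 / 10, 4:9 / 10), b2 = list(numeric(0), 1:5 / 10))
  eqn <- subsample_spikes(nested, seed = 3)
  expect_equal(length(unlist(eqn$b1)), 5)
  expect_equal(length(unlist(eqn$b2)), 5)
  expect_length(eqn$b1, 2)
  expect_error(subsample_spikes(list(1:3 / 10, numeric(0))),
               class = "spikefield_empty_block")
})

test_that("the coherence z-transform matches its closed forms", {
  expect_equal(coherence_z(0, 100), -1.3225, tolerance = 1e-10)
  expect_equal(coherence_z(0.5, 50), 1.15 * (-48 * log(0.75) - 1.15),
               tolerance = 1e-12)
  expect_equal(coherence_z(0.5, 50), 14.5576, tolerance = 1e-4)
  expect_error(coherence_z(0.5, 2), "V")
  expect_true(is.na(coherence_z(1, 50)))
  est <- list(frequencies = c(3.3, 6.6), sfc = c(0.25, 1), n_tapers = c(1, 1),
              V = c(50, 50), n_spikes = 50)
  class(est) <- "coherence_estimate"
  zc <- z_transform_sfc(est)
  expect_equal(zc$z[1], coherence_z(0.5, 50))  # sfc is |C|^2
  expect_true(is.na(zc$z[2]))                  # perfect coherence masked
})

test_that("null z is centred with variance near 1 at theta (small-scale check)", {
  zs <- simulate_null_z(n_rep = 40, n_spikes = 400, duration = 400, seed = 3)
  expect_lt(abs(mean(zs)), 0.6)
  expect_gt(var(zs), 0.3)
  expect_lt(var(zs), 3)
})

test_that("trial-shuffled SFC collapses coupling but preserves null level", {
  # two identical trials: any permutation reproduces the unshuffled SFC
  lfp <- sinusoid_lfp(6, dur = 6)
  st <- peak_spikes(6, 30)
  same <- shuffle_control_sfc(list(st, st), list(lfp, lfp), n_shuffles = 5,
                              seed = 1)
  direct <- compute_sfc(list(st, st), list(lfp, lfp))
  expect_equal(same$sfc, direct$sfc, tolerance = 1e-12)
  # coupled trials with independent oscillator phases: shuffling collapses
  # theta SFC toward the null
  cfg <- session_config(n_blocks = 1, trials_per_block = 8,
                        orientations = c(0, 5), delay_ms = 3000, seed = 77)
  prof <- coupling_profile(kappa = 2, base_rate = 15, noise_sd = 0.4)
  lfps <- lapply(1:8, function(i) generate_lfp(cfg, prof, i))
  spikes <- lapply(1:8, function(i) {
    generate_spikes(lfps[[i]], prof, seed = 300 + i)
  })
  obs <- compute_sfc(spikes, lfps)
  shuf <- shuffle_control_sfc(spikes, lfps, n_shuffles = 30, seed = 2)
  th <- sfc_bands()$theta
  sel <- obs$frequencies >= th$low & obs$frequencies <= th$high
  expect_gt(mean(obs$sfc[sel]), 3 * mean(shuf$sfc[sel]))
  # uncoupled trials: shuffled and unshuffled estimate the same null
  prof0 <- coupling_profile(kappa = 0, base_rate = 15, noise_sd = 0.4)
  sp0 <- lapply(1:8, function(i) generate_spikes(lfps[[i]], prof0,
                                                 seed = 400 + i))
  obs0 <- compute_sfc(sp0, lfps)
  shuf0 <- shuffle_control_sfc(sp0, lfps, n_shuffles = 30, seed = 3)
  expect_lt(abs(mean(obs0$sfc[sel]) - mean(shuf0$sfc[sel])), 0.02)
  expect_error(shuffle_control_sfc(list(st), list(lfp)), "trials")
})

test_that("band averaging of coherence uses the in-band grid mean", {
  est <- compute_sfc(peak_spikes(6, 50), sinusoid_lfp(6, dur = 15))
  flat <- est
  flat$sfc <- rep(0.4, length(est$sfc))
  for (bd in sfc_bands()) expect_equal(band_average_sfc(flat, bd), 0.4)
  spot <- est
  spot$sfc <- as.numeric(abs(est$frequencies - 6.64) < 0.1) * 0.8
  expect_gt(band_average_sfc(spot, sfc_bands()$theta), 0)
  expect_equal(band_average_sfc(spot, sfc_bands()$gamma), 0)
  expect_error(band_average_sfc(est, band_definition("x", 499, 499.9)),
               "overlap")
})
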