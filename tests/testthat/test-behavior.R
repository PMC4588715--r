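# Psychometric curves, Weibull fits, thresholds, learning curves, strategy
# controls, and eye screening.

test_that("psychometric curve reports accuracies and the false-alarm rate", {
  tr <- data.frame(dtheta = rep(c(0, 3, 5, 10, 20), each = 20),
                   correct = TRUE)
  cv <- psychometric_curve(tr)
  expect_true(all(cv$accuracy == 1))
  expect_equal(attr(cv, "FA"), 0)
  tr$correct[tr$dtheta == 0][1:2] <- FALSE   # 2/20 errors at zero rotation
  cv2 <- psychometric_curve(tr)
  expect_equal(attr(cv2, "FA"), 0.1)
  expect_warning(psychometric_curve(data.frame(dtheta = c(3, 5, 10),
                                               correct = TRUE)), "false-alarm")
  # a simulated observer's curve sits within binomial error of the formula
  sim <- sim_observer_trials(192, FA = 0.1, a = 8, b = 2, seed = 71)
  cv3 <- psychometric_curve(sim)
  for (i in seq_len(nrow(cv3))) {
    p <- if (cv3$dtheta[i] == 0) 0.9 else weibull_p(cv3$dtheta[i], 0.1, 8, 2)
    expect_lt(abs(cv3$accuracy[i] - p), 3 * sqrt(p * (1 - p) / 192) + 0.01)
  }
})

test_that("Weibull fitting recovers parameters and flags degenerate data", {
  # exact (noise-free) data: recovery to numerical precision
  exact <- data.frame(dtheta = c(2, 4, 6, 9, 14, 20),
                      accuracy = weibull_p(c(2, 4, 6, 9, 14, 20), 0.1, 8, 1.6),
                      n = 50)
  attr(exact, "FA") <- 0.1
  f <- fit_weibull(exact)
  expect_true(f$converged)
  expect_equal(f$a, 8, tolerance = 1e-6)
  expect_equal(f$b, 1.6, tolerance = 1e-6)
  # binomial likelihood agrees closely on clean data
  fb <- fit_weibull(exact, method = "binomial")
  expect_equal(fb$a, 8, tolerance = 0.02)
  # a flat curve cannot identify the parameters
  flat <- data.frame(dtheta = c(3, 5, 10, 20), accuracy = 0.9, n = 50)
  attr(flat, "FA") <- 0.1
  ff <- fit_weibull(flat)
  expect_false(ff$converged && is.finite(ff$threshold75))
  expect_error(fit_weibull(exact[1:2, ], FA = 0.1), "levels")
})

test_that("a 960-trial session recovers a and b within 15%", {
  errs <- t(vapply(1:100, function(s) {
    sim <- sim_observer_trials(192, FA = 0.1, a = 8, b = 2, seed = s)
    f <- fit_weibull(psychometric_curve(sim))
    c(abs(f$a - 8) / 8, abs(f$b - 2) / 2)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.15)
  expect_lt(median(errs[, 2]), 0.15)
})

test_that("threshold inversion is exact and respects the FA domain", {
  expect_equal(threshold_from_fit(list(FA = 0, a = 5, b = 1)), 5 * log(4),
               tolerance = 1e-12)
  expect_equal(threshold_from_fit(list(FA = 0.25, a = 10, b = 1)),
               10 * log(3), tolerance = 1e-12)
  expect_equal(threshold_from_fit(list(FA = 0.1, a = 8, b = 2)),
               8 * sqrt(log(3.6)), tolerance = 1e-12)
  # P(threshold) = 0.75 exactly for random valid parameter draws
  set.seed(72)
  for (i in 1:50) {
    FA <- runif(1, 0, 0.6); a <- runif(1, 1, 25); b <- runif(1, 0.4, 4)
    thr <- threshold_from_fit(list(FA = FA, a = a, b = b))
    expect_equal(weibull_p(thr, FA, a, b), 0.75, tolerance = 1e-12)
  }
  expect_error(threshold_from_fit(list(FA = 0.8, a = 5, b = 1)), "undefined")
})

test_that("block thresholds track a stepping observer", {
  # emulates the observed regime: offset falling 18.9 -> 4.5 across blocks
  a_blocks <- c(18.9, 8, 6, 4.5)
  trials <- do.call(rbind, lapply(1:4, function(b) {
    d <- sim_observer_trials(48, FA = 0.1, a = a_blocks[b], b = 1.5,
                             seed = 80 + b)
    d$block <- b
    d
  }))
  bt <- block_thresholds(trials)
  expect_true(all(bt$converged))
  expect_gt(bt$threshold[1], bt$threshold[4])
  expect_equal(order(bt$threshold, decreasing = TRUE)[1], 1)
  # recovered relative decrease approximates the generative one
  rel_true <- (a_blocks[1] - a_blocks[4]) / a_blocks[1]
  rel_rec <- (bt$threshold[1] - bt$threshold[4]) / bt$threshold[1]
  expect_equal(rel_rec, rel_true, tolerance = 0.2)
  # stationary observer: thresholds stay in a tight range
  flat <- do.call(rbind, lapply(1:4, function(b) {
    d <- sim_observer_trials(48, FA = 0.1, a = 8, b = 1.5, seed = 90 + b)
    d$block <- b
    d
  }))
  bf <- block_thresholds(flat)
  expect_lt(diff(range(bf$threshold)), 0.5 * mean(bf$threshold))
})

test_that("sliding threshold has the expected window count and trend", {
  # arithmetic: floor((384 - 64)/10) + 1 = 33 windows
  a_blocks <- c(18.9, 8, 6, 4.5)
  trials <- do.call(rbind, lapply(1:4, function(b) {
    # block composition: 48 match + 12 per non-zero rotation = 96 trials
    dthetas <- c(rep(0, 48), rep(c(3, 5, 10, 20), each = 12))
    set.seed(100 + b)
    dthetas <- sample(dthetas)
    p <- ifelse(dthetas == 0, 0.9,
                weibull_p(pmax(dthetas, 1e-9), 0.1, a_blocks[b], 1.5))
    data.frame(block = b, dtheta = dthetas,
               correct = rbinom(96, 1, p) == 1)
  }))
  expect_equal(nrow(trials), 384)
  sl <- sliding_threshold(trials)
  expect_equal(nrow(sl$curve), 33)
  ok <- is.finite(sl$curve$threshold)
  first <- mean(head(sl$curve$threshold[ok], 5))
  last <- mean(tail(sl$curve$threshold[ok], 5))
  expect_gt(first, last)  # monotone decreasing fitted trend
  expect_true(sl$fit$converged)
  expect_gt(sl$fit$y0, sl$fit$y_inf)
  expect_error(sliding_threshold(trials[1:50, ]), "trials")
})

test_that("match-trial accuracy exposes a hold-bias strategy", {
  honest <- do.call(rbind, lapply(1:4, function(b) {
    d <- sim_observer_trials(48, FA = 0.1, a = 8, b = 1.5, seed = 110 + b)
    d$block <- b
    d
  }))
  mr <- match_rate_by_block(honest)
  expect_equal(nrow(mr$table), 4)
  expect_gt(mr$test$p.value, 0.05)
  # constructed positive control: match accuracy collapses over blocks
  biased <- honest
  drop_p <- c(0, 0.3, 0.6, 0.9)
  set.seed(111)
  for (b in 1:4) {
    sel <- biased$block == b & biased$dtheta == 0
    biased$correct[sel] <- runif(sum(sel)) > drop_p[b]
  }
  mrb <- match_rate_by_block(biased)
  expect_lt(mrb$test$p.value, 1e-6)
  expect_true(all(diff(mrb$table$accuracy) < 0.05))
})

test_that("microsaccade detection applies the inclusive velocity threshold", {
  rate <- 1000
  n <- 3000
  # velocity is sampled on the 10-ms tick grid (samples 1, 11, 21, ...), so
  # the step is placed to span exactly one tick-to-tick interval
  mk_step <- function(amp, at = 1491) {
    x <- numeric(n)
    x[at:(at + 10)] <- seq(0, amp, length.out = 11)
    x[(at + 11):n] <- amp
    list(x = x, y = numeric(n), rate = rate)
  }
  # 0.1 deg over one 10-ms interval: velocity exactly 10 deg/s, detected
  d1 <- detect_microsaccades(mk_step(0.1))
  expect_gte(nrow(d1$events), 1)
  expect_gte(max(d1$events$peak_velocity), 10)
  expect_false(d1$abort)
  # 0.3 deg: fixation instability, abort flag set
  d3 <- detect_microsaccades(mk_step(0.3))
  expect_true(d3$abort)
  # 0.05 deg (5 deg/s): below threshold
  d05 <- detect_microsaccades(mk_step(0.05))
  expect_equal(nrow(d05$events), 0)
  # smooth drift at 2 deg/s never crosses threshold
  drift <- list(x = 2 * (0:(n - 1)) / rate, y = numeric(n), rate = rate)
  expect_equal(nrow(detect_microsaccades(drift)$events), 0)
  expect_error(detect_microsaccades(list(x = 1:5, y = 1:5, rate = rate)),
               "shorter")
})

test_that("eye trend check flags only constructed block trends", {
  set.seed(112)
  stationary <- lapply(1:4, function(b) {
    data.frame(time = runif(20), amplitude = runif(20, 0.05, 0.15),
               peak_velocity = runif(20, 10, 20))
  })
  st <- eye_trend_check(stationary)
  expect_true(all(st$p.value > 0.05, na.rm = TRUE))
  trending <- lapply(1:4, function(b) {
    data.frame(time = runif(20), amplitude = 0.05 + 0.04 * b +
                 runif(20, 0, 0.01), peak_velocity = runif(20, 10, 20))
  })
  tr <- eye_trend_check(trending)
  amp_row <- tr[tr$measure == "amplitude", ]
  expect_gt(amp_row$r, 0.9)
  expect_lt(amp_row$p.value, 0.05)
  expect_error(eye_trend_check(stationary[1]), "blocks")
  empty <- eye_trend_check(lapply(1:4, function(b) {
    data.frame(time = numeric(0), amplitude = numeric(0))
  }))
  expect_equal(nrow(empty), 0)
})
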