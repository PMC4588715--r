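# Psychometric curves, Weibull threshold fitting, learning curves,
# strategy controls, and microsaccade screening.

#' Weibull psychometric function
#'
#' `P(dtheta) = 1 - (1 - FA) * exp(-(dtheta / a)^b)`, with offset `a` and
#' slope `b`: the probability of judging the test stimulus "different".
#' For any non-zero rotation this is the probability of a correct
#' response; at `dtheta = 0` it equals the false-alarm rate `FA` (the
#' error rate on match trials), so match-trial accuracy is `1 - FA`.
#'
#' @param dtheta rotation in degrees (>= 0)
#' @param FA false-alarm probability in [0, 1)
#' @param a offset term, degrees > 0
#' @param b slope term > 0
#' @return probability of a "different" judgment (correct response for
#'   `dtheta > 0`)
#' @export
weibull_p <- function(dtheta, FA, a, b) {
  stopifnot(FA >= 0, FA < 1, a > 0, b > 0)
  1 - (1 - FA) * exp(-(dtheta / a)^b)
}

#' Per-orientation accuracy table
#'
#' Averages the correct-response rate for each orientation difference
#' between target and test. The false-alarm rate is the error rate at zero
#' rotation (match trials); if no match trials are present it is flagged
#' unavailable.
#'
#' @param trials data.frame with columns `dtheta` (degrees) and `correct`
#'   (logical/0-1)
#' @return data.frame with `dtheta`, `n`, `accuracy`; attribute `FA` holds
#'   the false-alarm rate (or `NA` with a warning if unavailable)
#' @export
psychometric_curve <- function(trials) {
  stopifnot(all(c("dtheta", "correct") %in% names(trials)))
  agg <- aggregate(cbind(correct = trials$correct),
                   by = list(dtheta = trials$dtheta), FUN = mean)
  n <- as.integer(table(factor(trials$dtheta, levels = sort(unique(trials$dtheta)))))
  curve <- data.frame(dtheta = agg$dtheta, n = n, accuracy = agg$correct)
  curve <- curve[order(curve$dtheta), , drop = FALSE]
  if (any(curve$dtheta == 0)) {
    FA <- 1 - curve$accuracy[curve$dtheta == 0]
  } else {
    warning("no zero-rotation trials: false-alarm rate unavailable")
    FA <- NA_real_
  }
  attr(curve, "FA") <- FA
  curve
}

#' Fit the Weibull psychometric function
#'
#' Estimates `a` and `b` by least squares on the per-orientation accuracies
#' with `FA` fixed to the observed false-alarm rate (the zero-rotation
#' error rate is a direct observation, not a free parameter). A
#' binomial-likelihood fit weighted by trial counts is available as an
#' option. Non-convergence (or a degenerate flat curve) is flagged and the
#' threshold withheld.
#'
#' @param curve accuracy table from [psychometric_curve()] (or a data.frame
#'   with `dtheta`, `accuracy`, optional `n`)
#' @param FA false-alarm rate; defaults to the curve's `FA` attribute
#' @param method `"ls"` (least squares on accuracies) or `"binomial"`
#'   (maximum likelihood with per-level trial counts)
#' @return object of class `psychometric_fit`: `FA`, `a`, `b`,
#'   `threshold75`, `converged`, `residual`
#' @export
fit_weibull <- function(curve, FA = attr(curve, "FA"),
                        method = c("ls", "binomial")) {
  method <- match.arg(method)
  if (is.null(FA) || is.na(FA)) stop("false-alarm rate required for the fit")
  d <- curve[curve$dtheta > 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need >= 3 non-zero rotation levels")
  start <- list(a = max(median(d$dtheta), 1e-3), b = 1)
  fit <- NULL
  if (method == "ls") {
    fit <- tryCatch(
      minpack.lm::nlsLM(accuracy ~ 1 - (1 - FA) * exp(-(dtheta / a)^b),
                        data = d, start = start,
                        lower = c(a = 1e-6, b = 1e-6),
                        upper = c(a = 1e4, b = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    if (is.null(d$n)) stop("binomial fitting needs per-level trial counts n")
    nll <- function(par) {
      p <- pmin(pmax(weibull_p(d$dtheta, FA, exp(par[1]), exp(par[2])),
                     1e-9), 1 - 1e-9)
      -sum(d$n * (d$accuracy * log(p) + (1 - d$accuracy) * log(1 - p)))
    }
    op <- tryCatch(stats::optim(log(c(start$a, start$b)), nll),
                   error = function(e) NULL)
    if (!is.null(op) && op$convergence == 0) {
      fit <- list(a = exp(op$par[1]), b = exp(op$par[2]), value = op$value)
    }
  }
  if (is.null(fit)) {
    return(structure(list(FA = FA, a = NA_real_, b = NA_real_,
                          threshold75 = NA_real_, converged = FALSE,
                          residual = NA_real_, method = method),
                     class = "psychometric_fit"))
  }
  if (method == "ls") {
    a <- coef(fit)[["a"]]; b <- coef(fit)[["b"]]
    resid <- sqrt(mean(residuals(fit)^2))
  } else {
    a <- fit$a; b <- fit$b; resid <- fit$value
  }
  # a pinned at a bound or a flat curve signals a degenerate fit
  converged <- is.finite(a) && is.finite(b) && a < 9e3 &&
    diff(range(d$accuracy)) > 1e-6
  out <- structure(list(FA = FA, a = a, b = b, threshold75 = NA_real_,
                        converged = converged, residual = resid,
                        method = method),
                   class = "psychometric_fit")
  if (converged && FA < 0.75) out$threshold75 <- threshold_from_fit(out)
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> FA = %.3f, a = %.3g, b = %.3g, 75%% threshold = %.3g deg%s\n",
              x$FA, x$a, x$b, x$threshold75,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' 75% discrimination threshold from a Weibull fit
#'
#' Closed-form inversion of the psychometric function at 75% accuracy,
#' accounting for the false-alarm rate:
#' `threshold = a * (log((1 - FA) / 0.25))^(1/b)`, so that
#' `P(threshold) = 0.75` exactly. Undefined (error) when `FA >= 0.75`.
#'
#' @param fit a `psychometric_fit`, or a list with `FA`, `a`, `b`
#' @param level accuracy level defining the threshold (default 0.75)
#' @return threshold in degrees
#' @export
threshold_from_fit <- function(fit, level = 0.75) {
  if (fit$FA >= level) stop(sprintf("threshold undefined: FA = %.2f >= %g",
                                    fit$FA, level))
  fit$a * (log((1 - fit$FA) / (1 - level)))^(1 / fit$b)
}

#' Per-block psychometric fits and thresholds
#'
#' Fits the Weibull function separately in each trial block and returns
#' the block thresholds. Blocks failing the fit preconditions are flagged
#' (`converged = FALSE`) and should be excluded from trend statistics.
#'
#' @param trials data.frame with `block`, `dtheta`, `correct`
#' @param ... passed to [fit_weibull()]
#' @return data.frame with one row per block: `block`, `FA`, `a`, `b`,
#'   `threshold`, `converged`; attribute `fits` keeps the full fit objects
#' @export
block_thresholds <- function(trials, ...) {
  stopifnot("block" %in% names(trials))
  blocks <- sort(unique(trials$block))
  fits <- lapply(blocks, function(b) {
    d <- trials[trials$block == b, , drop = FALSE]
    tryCatch(fit_weibull(psychometric_curve(d), ...),
             error = function(e) NULL)
  })
  row_of <- function(f, b) {
    if (is.null(f)) {
      data.frame(block = b, FA = NA, a = NA, b = NA, threshold = NA,
                 converged = FALSE)
    } else {
      data.frame(block = b, FA = f$FA, a = f$a, b = f$b,
                 threshold = f$threshold75, converged = f$converged)
    }
  }
  out <- do.call(rbind, mapply(row_of, fits, blocks, SIMPLIFY = FALSE))
  attr(out, "fits") <- fits
  out
}

#' Sliding-window learning curve of the discrimination threshold
#'
#' Recomputes the Weibull threshold in a sliding window of trials (default
#' 64 trials stepped by 10) over the session, then fits the exponential
#' learning curve `y(t) = y_inf + (y0 - y_inf) * exp(-t / tau)` to the
#' threshold-versus-trial curve. Windows whose fit fails are masked.
#'
#' @param trials data.frame with `dtheta`, `correct`, in presentation order
#' @param window window length in trials
#' @param step step between window starts, in trials
#' @param ... passed to [fit_weibull()]
#' @return list with `curve` (data.frame: `center` trial index,
#'   `threshold`) and `fit` (exponential fit parameters `y0`, `y_inf`,
#'   `tau`, plus `converged`)
#' @export
sliding_threshold <- function(trials, window = 64, step = 10, ...) {
  n <- nrow(trials)
  if (n < window) stop(sprintf("need >= %d trials", window))
  starts <- seq(1, n - window + 1, by = step)
  thr <- vapply(starts, function(s) {
    d <- trials[s:(s + window - 1), , drop = FALSE]
    f <- tryCatch(fit_weibull(psychometric_curve(d), ...),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged || !is.finite(f$threshold75)) NA_real_
    else f$threshold75
  }, numeric(1))
  curve <- data.frame(center = starts + (window - 1) / 2, threshold = thr)
  ok <- is.finite(curve$threshold)
  expfit <- list(y0 = NA_real_, y_inf = NA_real_, tau = NA_real_,
                 converged = FALSE)
  if (sum(ok) >= 4) {
    d <- curve[ok, , drop = FALSE]
    y0_init <- d$threshold[1]
    yinf_init <- mean(tail(d$threshold, 3))
    fit <- tryCatch(
      minpack.lm::nlsLM(threshold ~ y_inf + (y0 - y_inf) * exp(-center / tau),
                        data = d,
                        start = list(y0 = y0_init, y_inf = yinf_init,
                                     tau = max(diff(range(d$center)) / 3, 1)),
                        lower = c(y0 = 0, y_inf = 0, tau = 1e-2),
                        upper = c(y0 = Inf, y_inf = Inf, tau = 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      expfit <- list(y0 = cf[["y0"]], y_inf = cf[["y_inf"]],
                     tau = cf[["tau"]], converged = TRUE)
    }
  }
  list(curve = curve, fit = expfit)
}

#' Match-trial accuracy per block
#'
#' Block-by-block proportion correct on match (zero-rotation, bar-release)
#' trials, with an equality test across blocks. A monkey drifting toward a
#' hold-everything strategy would show collapsing match accuracy, so this
#' is the strategy control for apparent threshold improvements.
#'
#' @param trials data.frame with `block`, `dtheta`, `correct`
#' @return list with `table` (per block: `n`, `accuracy`) and `test`
#'   (chi-squared equality of proportions across blocks)
#' @export
match_rate_by_block <- function(trials) {
  m <- trials[trials$dtheta == 0, , drop = FALSE]
  if (nrow(m) == 0L) stop("no match trials")
  blocks <- sort(unique(m$block))
  tab <- do.call(rbind, lapply(blocks, function(b) {
    d <- m[m$block == b, , drop = FALSE]
    data.frame(block = b, n = nrow(d), accuracy = mean(d$correct))
  }))
  test <- if (length(blocks) >= 2) {
    suppressWarnings(stats::prop.test(
      x = round(tab$accuracy * tab$n), n = tab$n))
  } else NULL
  list(table = tab, test = test)
}

#' Detect microsaccades from an eye trace
#'
#' Screens fixation stability every 10 ms: the vector velocity between
#' consecutive 10-ms positions is displacement / 0.010 s, and intervals
#' with velocity at or above `velocity_threshold` (10 deg/s corresponds
#' exactly to a 0.1 deg movement between consecutive 10-ms samples; the
#' crossing is inclusive) are merged into events. A trial is flagged for
#' abort iff any event's total amplitude exceeds `abort_amplitude`
#' (0.25 deg fixation instability).
#'
#' @param eye list with `x`, `y` position series in degrees at `rate` Hz
#'   (an `eye_trace` from [generate_eye_trace()] works directly)
#' @param rate sampling rate of the position series
#' @param velocity_threshold detection threshold in deg/s (inclusive)
#' @param abort_amplitude amplitude above which the trial is aborted, deg
#' @return list with `events` (data.frame: `time` s, `duration` s,
#'   `amplitude` deg, `peak_velocity` deg/s), `abort` flag, and the
#'   10-ms `velocity` series
#' @export
detect_microsaccades <- function(eye, rate = 1000, velocity_threshold = 10,
                                 abort_amplitude = 0.25) {
  x <- eye$x; y <- eye$y
  if (!is.null(eye$rate)) rate <- eye$rate
  n <- length(x)
  step <- as.integer(round(0.010 * rate))
  if (n < 2L * step) stop("trace shorter than two 10-ms intervals")
  idx <- seq(1L, n, by = step)
  xs <- x[idx]; ys <- y[idx]
  vel <- sqrt(diff(xs)^2 + diff(ys)^2) / 0.010
  hot <- vel >= velocity_threshold
  events <- data.frame(time = numeric(0), duration = numeric(0),
                       amplitude = numeric(0), peak_velocity = numeric(0))
  if (any(hot)) {
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      amp <- sqrt((xs[i1 + 1] - xs[i0])^2 + (ys[i1 + 1] - ys[i0])^2)
      events <- rbind(events, data.frame(
        time = (idx[i0] - 1) / rate,
        duration = (i1 - i0 + 1) * 0.010,
        amplitude = amp,
        peak_velocity = max(vel[i0:i1])))
    }
  }
  list(events = events,
       abort = nrow(events) > 0 && any(events$amplitude > abort_amplitude),
       velocity = vel)
}

#' Block trend in microsaccade amplitude and frequency
#'
#' Correlates per-block mean event amplitude and event rate against block
#' index (Pearson), the control that apparent learning effects are not eye
#' movement artifacts.
#'
#' @param events_by_block list per block of event data.frames from
#'   [detect_microsaccades()] (pooled over the block's trials)
#' @return data.frame with one row per measure (`amplitude`, `frequency`):
#'   correlation `r` and `p.value`; empty report if no events anywhere
#' @export
eye_trend_check <- function(events_by_block) {
  nb <- length(events_by_block)
  if (nb < 2L) stop("need >= 2 blocks")
  counts <- vapply(events_by_block, function(e) if (is.null(e)) 0L else nrow(e),
                   integer(1))
  if (sum(counts) == 0L) {
    return(data.frame(measure = character(0), r = numeric(0),
                      p.value = numeric(0)))
  }
  amp <- vapply(events_by_block, function(e) {
    if (is.null(e) || nrow(e) == 0) NA_real_ else mean(e$amplitude)
  }, numeric(1))
  blk <- seq_len(nb)
  out <- data.frame(measure = c("amplitude", "frequency"),
                    r = NA_real_, p.value = NA_real_)
  ok <- is.finite(amp)
  if (sum(ok) >= 3) {
    ct <- cor.test(blk[ok], amp[ok])
    out$r[1] <- unname(ct$estimate); out$p.value[1] <- ct$p.value
  }
  if (length(unique(counts)) > 1) {
    ct <- cor.test(blk, counts)
    out$r[2] <- unname(ct$estimate); out$p.value[2] <- ct$p.value
  }
  out
}
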