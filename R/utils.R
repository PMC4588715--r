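# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All randomness in the synthetic-data generator flows from a single session
#' seed. Each component (LFP noise, spiking, behavior, eye traces, ...) draws
#' from its own substream so that any single trial can be regenerated in
#' isolation. Substream seeds are produced by a small integer hash of the
#' master seed, a stream label, and an index, reduced modulo 2^31 - 1.
#'
#' @param seed master integer seed
#' @param stream character label of the random stream
#' @param index integer index within the stream (e.g. trial number)
#' @return an integer seed suitable for [set.seed()]
#' @export
split_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  # stay well inside 2^53 so the double arithmetic is exact
  s <- (abs(seed) %% 2147483647) * 69069 + h * 30011 + (index %% 1e6) * 2654435
  as.integer(s %% 2147483647)
}

#' Analytic signal by FFT half-spectrum doubling
#'
#' Computes the discrete analytic signal whose real part is the input and
#' whose argument gives the instantaneous phase. Standard construction:
#' double the positive-frequency half of the spectrum, zero the negative
#' half, keep DC (and Nyquist for even length) unchanged.
#'
#' @param x real numeric vector
#' @return complex vector of the same length
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# signed circular distance a - b in (-pi, pi]
circ_dist <- function(a, b) wrap_angle(a - b)

# circular mean direction
circ_mean <- function(a) Arg(mean(exp(1i * a)))

# mean resultant length
circ_r <- function(a) Mod(mean(exp(1i * a)))

# circular median: direction minimizing the mean absolute circular deviation,
# searched over the observed angles (P-median convention)
circ_median <- function(a) {
  if (length(a) == 0L) stop("empty angle set")
  dev <- vapply(a, function(m) mean(abs(circ_dist(a, m))), numeric(1))
  cands <- a[dev <= min(dev) + 1e-12]
  # average the tied candidates on the circle
  Arg(mean(exp(1i * cands)))
}
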