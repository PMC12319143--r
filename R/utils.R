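# Small numerical helpers shared across modules. All times in ms, lengths in m.

#' Centred moving average with shrinking windows at the boundaries
#'
#' @param x numeric vector.
#' @param window odd window length in samples; `window = 1` returns `x`.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
moving_average <- function(x, window = 5L) {
  n <- length(x)
  if (window <= 1L || n < 3L) return(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Central-difference derivative with one-sided differences at the ends.
# t and x must have equal length >= 2; t strictly increasing.
finite_diff <- function(x, t) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  if (n == 2L) {
    d[] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
    return(d)
  }
  i <- 2:(n - 1L)
  d[i] <- (x[i + 1L] - x[i - 1L]) / (t[i + 1L] - t[i - 1L])
  d[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  d
}

# Linear interpolation of x at time t0 (t increasing); clamps outside the range.
interp_at <- function(t, x, t0) {
  stats::approx(t, x, xout = t0, rule = 2)$y
}

# Truncated-normal draw by rejection/clamping: redraw a bounded number of times,
# then clamp. Keeps the RNG stream finite and deterministic.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

# Sample standard deviation (n - 1 denominator), NA-safe.
sd_sample <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
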