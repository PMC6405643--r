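#' Normalize a series to zero mean and unit standard deviation
#'
#' DFA itself does not require normalization, but dividing by the series'
#' standard deviation makes the residual-variance precision thresholds
#' (see [default_thresholds()]) independent of the measurement units, so
#' blocks with very low dynamics can be recognized on an absolute scale.
#' The population standard deviation (divisor \code{N}) is used.
#'
#' @param raw Numeric vector, the observed series (at least 16 samples).
#' @return An object of class \code{mfdfa_norm}: a list with \code{values}
#'   (zero-mean, unit-SD series), \code{mu_S} and \code{sigma_S} (original
#'   mean and population SD), and \code{N}.
#' @examples
#' z <- normalize_series(rnorm(100, mean = 60, sd = 5))
#' c(mean(z$values), sd(z$values))  # ~0, ~1
#' @export
normalize_series <- function(raw) {
  if (!is.numeric(raw)) stop("'raw' must be numeric")
  if (anyNA(raw)) stop("'raw' contains NA values; clean the series first")
  N <- length(raw)
  if (N < 16L) stop("series too short: need at least 16 samples, got ", N)
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))
  if (sigma <= 0) stop("constant series: standard deviation is zero, cannot normalize")
  structure(
    list(values = (raw - mu) / sigma, mu_S = mu, sigma_S = sigma, N = N),
    class = "mfdfa_norm"
  )
}

#' Cumulative profile of a normalized series
#'
#' The profile \eqn{y_i = \sum_{j \le i} s_j} is the object that is actually
#' detrended by DFA: a series behaving like noise has a profile behaving like
#' a random walk, shifting the scaling exponent by one.
#'
#' @param s An \code{mfdfa_norm} object from [normalize_series()], or a plain
#'   numeric vector (taken as already normalized).
#' @return Numeric vector \code{y} of cumulative sums, same length as input.
#' @export
cumulative_profile <- function(s) {
  v <- if (inherits(s, "mfdfa_norm")) s$values else s
  if (!is.numeric(v)) stop("input must be numeric or an 'mfdfa_norm' object")
  cumsum(v)
}
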