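#' Seeded generators for fractal and multifractal validation series
#'
#' Reference stochastic processes with known scaling behaviour, used to
#' validate the estimator:
#' \describe{
#'   \item{\code{"white"}}{white Gaussian noise, zero mean, variance
#'     \code{var} (default 1); alpha = 0.5.}
#'   \item{\code{"brownian"}}{Brownian motion as the running integral of a
#'     zero-mean white noise with increment variance \code{var} (default 1);
#'     alpha = 1.5.}
#'   \item{\code{"wb"}}{superposition of unit-variance white noise and an
#'     independent Brownian motion with increment variance 0.01986918, which
#'     places the white/brown spectral crossover at f = 10^-2.5, i.e. a
#'     crossover scale of about 316 samples.}
#'   \item{\code{"ar1"}}{first-order autoregression x_i = a x_{i-1} + wn_i
#'     driven by unit-variance Gaussian noise; default a = 0.9391014, a
#'     low-pass with cut-off 0.01 (crossover scale about 100), so the slope
#'     tends to 0.5 at the largest scales.}
#'   \item{\code{"cauchy"}}{i.i.d. Cauchy samples, location 0, scale 3
#'     (heavy-tailed multifractal test case).}
#'   \item{\code{"cascade"}}{binomial multiplicative cascade embedded in
#'     noise: starting from 2^steps ones, each segment is recursively halved
#'     and one random half multiplied by \code{weight} (default 0.25), the
#'     other by 1 - weight, for \code{steps} levels; values below
#'     \code{noise_floor} (1e-6) are replaced by uniform noise on
#'     (0, \code{noise_max} = 0.01); finally the reversed duplicate is
#'     subtracted to symmetrize the distribution.  \code{cascades} > 1
#'     concatenates independent cascades of length N/cascades each.}
#' }
#'
#' @param model One of \code{"white"}, \code{"brownian"}, \code{"wb"},
#'   \code{"ar1"}, \code{"cauchy"}, \code{"cascade"}.
#' @param N Series length; for \code{"cascade"}, N/cascades must be a power
#'   of 2.
#' @param seed Optional integer seed (deterministic output when given).
#' @param var Variance (white) or increment variance (brownian).
#' @param a AR(1) coefficient.
#' @param location,scale Cauchy parameters.
#' @param weight,noise_floor,noise_max,cascades Cascade parameters.
#' @param raw_cascade If TRUE, return the cascade before noise-flooring and
#'   symmetrization (its 2^steps values sum to 1 exactly — mass conservation
#'   of the multiplicative construction).
#' @return Numeric vector of length N.
#' @examples
#' x <- gen_series("ar1", 4096, seed = 7)
#' @export
gen_series <- function(model, N, seed = NULL, var = 1, a = 0.9391014,
                       location = 0, scale = 3, weight = 0.25,
                       noise_floor = 1e-6, noise_max = 0.01,
                       cascades = 1L, raw_cascade = FALSE) {
  model <- match.arg(model, c("white", "brownian", "wb", "ar1", "cauchy", "cascade"))
  N <- as.integer(N)
  if (N < 1L) stop("N must be positive")
  if (!is.null(seed)) set.seed(seed)
  switch(model,
    white = stats::rnorm(N, 0, sqrt(var)),
    brownian = cumsum(stats::rnorm(N, 0, sqrt(var))),
    wb = stats::rnorm(N) + cumsum(stats::rnorm(N, 0, sqrt(0.01986918))),
    ar1 = as.numeric(stats::filter(stats::rnorm(N), a, method = "recursive")),
    cauchy = stats::rcauchy(N, location, scale),
    cascade = {
      if (cascades < 1L || N %% cascades != 0L) {
        stop("N must be a multiple of 'cascades'")
      }
      len <- N %/% cascades
      out <- lapply(seq_len(cascades), function(i) {
        binomial_cascade(len, weight, noise_floor, noise_max, raw_cascade)
      })
      unlist(out, use.names = FALSE)
    }
  )
}

# One binomial multiplicative cascade of length n = 2^k (noise-embedded,
# antisymmetrized unless raw = TRUE).
binomial_cascade <- function(n, weight, noise_floor, noise_max, raw = FALSE) {
  k <- as.integer(round(log2(n)))
  if (2^k != n) stop("cascade length must be a power of 2, got ", n)
  v <- rep(1, n)
  for (s in seq_len(k)) {
    half <- n %/% 2^s
    nseg <- 2^(s - 1)
    flip <- stats::runif(nseg) < 0.5          # which half gets 'weight'
    w1 <- ifelse(flip, weight, 1 - weight)
    wvec <- rep(as.vector(rbind(w1, 1 - w1)), each = half)
    v <- v * wvec
  }
  if (raw) return(v)
  low <- v < noise_floor
  if (any(low)) v[low] <- stats::runif(sum(low), 0, noise_max)
  v - rev(v)
}
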