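#' Default precision thresholds for the fast residual-variance formulas
#'
#' When the analytically computed residual variance of a block is very small,
#' rounding error in the prefix-sum differences can dominate the estimate.
#' Variances below a length-dependent threshold are therefore recomputed by
#' direct summation over the block.  Because the series is normalized to unit
#' SD the thresholds depend only on the series length \code{N} and on the
#' detrending order: \code{Th1 = 1e-3} for \code{N <= 1e5}, else \code{N/1e8};
#' \code{Th2 = 1e-2} for \code{N <= 1e2}, else \code{N/1e4}.
#'
#' \code{EPS} addresses a different problem: blocks whose residual variance is
#' genuinely tiny (overfit smallest blocks, low-pass-filtered data) distort
#' \eqn{F_q} at negative \code{q}; variances below \code{EPS} are discarded.
#' Its default is 0 (keep everything); a typical value for filtered
#' biomedical data is 1e-4 of the normalized dynamics.
#'
#' @param N Series length (>= 16).
#' @param eps Discard threshold for low-variance blocks (default 0).
#' @return List with \code{th1}, \code{th2}, \code{eps}.
#' @examples
#' default_thresholds(1e4)  # th1 = 1e-3, th2 = 1
#' @export
default_thresholds <- function(N, eps = 0) {
  if (N < 16) stop("N must be at least 16")
  list(
    th1 = if (N <= 1e5) 1e-3 else N / 1e8,
    th2 = if (N <= 1e2) 1e-2 else N / 1e4,
    eps = eps
  )
}

#' Analytic least-squares polynomial fit of one profile block
#'
#' Fits \eqn{y = b_1 j + a_1} (order 1) or \eqn{y = c_2 j^2 + b_2 j + a_2}
#' (order 2) to a block in its local index \code{j = 1..n}, using the
#' closed-form normal-equation solution in which every design-matrix moment
#' is a Faulhaber sum and the data moments are plain sums.  Working in the
#' local index (rather than the global sample index) avoids subtracting
#' near-equal huge numbers for blocks deep into a long series.
#'
#' @param z Numeric vector: the block's profile values, local index 1..n.
#' @param order Detrending order, 1 or 2.
#' @return Named coefficient vector: \code{c(a, b)} or \code{c(a, b, c)},
#'   with \code{a} the intercept.
#' @examples
#' fit_block_poly(2 * (1:10) + 3, 1)      # b = 2, a = 3
#' fit_block_poly((1:10)^2, 2)            # c = 1, b = 0, a = 0
#' @export
fit_block_poly <- function(z, order) {
  n <- length(z)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (n < order + 2) stop("degenerate fit: need n >= order + 2")
  j <- as.numeric(seq_len(n))
  mj <- (n + 1) / 2                       # mean of j
  mj2 <- power_sum(2, n) / n              # mean of j^2
  ybar <- sum(z) / n
  Sii <- mj2 - mj^2
  Siy <- sum(j * z) / n - mj * ybar
  if (order == 1L) {
    b <- Siy / Sii
    return(c(a = ybar - b * mj, b = b))
  }
  Sii2 <- power_sum(3, n) / n - mj * mj2
  Si2i2 <- power_sum(4, n) / n - mj2^2
  Si2y <- sum(j * j * z) / n - mj2 * ybar
  den <- Sii * Si2i2 - Sii2^2
  cc <- (Si2y * Sii - Siy * Sii2) / den
  b <- (Siy * Si2i2 - Si2y * Sii2) / den
  c(a = ybar - b * mj - cc * mj2, b = b, c = cc)
}

#' Residual variance of a detrended block, fast analytic form
#'
#' Expands \eqn{\sigma^2 = \frac1n \sum_j (z_j - p(j))^2} so that only block
#' moments (sums of \eqn{j^V z_j^W}) appear — no per-sample residual loop.
#' If the analytic value falls below the precision threshold for the given
#' order, it is recomputed by direct summation of the squared residuals
#' (with a fresh direct fit), which bounds the rounding error.  A residual
#' negative value beyond -1e-9 indicates a precision failure and is clipped
#' to zero with a warning.
#'
#' @param z Block profile values (local index 1..n).
#' @param order Detrending order, 1 or 2.
#' @param th Recompute threshold; defaults from [default_thresholds()] need
#'   the full series length, so pass the relevant \code{th1}/\code{th2} here
#'   (default 0 disables the recompute).
#' @param coef Optional precomputed coefficients from [fit_block_poly()].
#' @return Scalar residual variance (>= 0).
#' @export
residual_variance_fast <- function(z, order, th = 0, coef = NULL) {
  n <- length(z)
  if (is.null(coef)) coef <- fit_block_poly(z, order)
  j <- as.numeric(seq_len(n))
  S0 <- sum(z); S1 <- sum(j * z); Sq <- sum(z * z)
  if (order == 1L) {
    a <- coef[["a"]]; b <- coef[["b"]]
    v <- a^2 + (Sq + b^2 * power_sum(2, n) + 2 * a * b * power_sum(1, n) -
                  2 * b * S1 - 2 * a * S0) / n
  } else {
    a <- coef[["a"]]; b <- coef[["b"]]; cc <- coef[["c"]]
    S2 <- sum(j * j * z)
    v <- a^2 +
      (cc^2 * power_sum(4, n) + 2 * cc * b * power_sum(3, n) +
         (b^2 + 2 * a * cc) * power_sum(2, n) + 2 * b * a * power_sum(1, n)) / n +
      (Sq - 2 * cc * S2 - 2 * b * S1 - 2 * a * S0) / n
  }
  if (v < th) {
    cf <- fit_block_poly(z, order)
    fitted <- if (order == 1L) cf[["a"]] + cf[["b"]] * j
              else cf[["a"]] + cf[["b"]] * j + cf[["c"]] * j * j
    v <- sum((z - fitted)^2) / n
  }
  if (v < 0) {
    if (v < -1e-9) warning("negative residual variance beyond tolerance (precision failure); clipped to 0")
    v <- 0
  }
  v
}

# Vectorized fast residual variances for all blocks at one scale.
# Returns list(v1 = ..., v2 = ...) for the requested orders; blocks whose
# analytic variance falls below the order's threshold are recomputed in the
# compiled direct-summation kernel.
block_variances_fast <- function(store, y, scheme, orders, th) {
  n <- scheme$n
  I <- as.numeric(scheme$I)
  d <- I - 1
  S0  <- block_moment(store, 0, 1, scheme$I, n)
  S1g <- block_moment(store, 1, 1, scheme$I, n)
  S2g <- block_moment(store, 2, 1, scheme$I, n)
  Sq  <- block_moment(store, 0, 2, scheme$I, n)
  # shift global-index moments to the local index j = 1..n
  S1 <- S1g - d * S0
  S2 <- S2g - 2 * d * S1g + d * d * S0
  P1 <- power_sum(1, n); P2 <- power_sum(2, n)
  P3 <- power_sum(3, n); P4 <- power_sum(4, n)
  mj <- (n + 1) / 2
  mj2 <- P2 / n
  ybar <- S0 / n
  Sii <- mj2 - mj^2
  Siy <- S1 / n - mj * ybar
  out <- list()
  if (1L %in% orders) {
    b1 <- Siy / Sii
    a1 <- ybar - b1 * mj
    v1 <- a1^2 + (Sq + b1^2 * P2 + 2 * a1 * b1 * P1 - 2 * b1 * S1 - 2 * a1 * S0) / n
    out$v1 <- recompute_low(v1, y, scheme$I, n, 1L, th$th1)
  }
  if (2L %in% orders) {
    Sii2 <- P3 / n - mj * mj2
    Si2i2 <- P4 / n - mj2^2
    Si2y <- S2 / n - mj2 * ybar
    den <- Sii * Si2i2 - Sii2^2
    c2 <- (Si2y * Sii - Siy * Sii2) / den
    b2 <- (Siy * Si2i2 - Si2y * Sii2) / den
    a2 <- ybar - b2 * mj - c2 * mj2
    v2 <- a2^2 +
      (c2^2 * P4 + 2 * c2 * b2 * P3 + (b2^2 + 2 * a2 * c2) * P2 + 2 * b2 * a2 * P1) / n +
      (Sq - 2 * c2 * S2 - 2 * b2 * S1 - 2 * a2 * S0) / n
    out$v2 <- recompute_low(v2, y, scheme$I, n, 2L, th$th2)
  }
  out
}

recompute_low <- function(v, y, I, n, order, th) {
  low <- which(!is.finite(v) | v < th)
  if (length(low)) {
    v[low] <- direct_variances_cpp(y, I[low], n, order)
  }
  neg <- v < 0
  if (any(v < -1e-9)) {
    warning("negative residual variances beyond tolerance at n = ", n,
            " (order ", order, "); clipped to 0")
  }
  v[neg] <- 0
  v
}
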