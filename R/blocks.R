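#' Block segmentation scheme for a given scale and overlap
#'
#' The profile is split into \code{M} blocks of size \code{n} whose starts
#' advance by \code{n - L} samples, where \code{L} is the number of samples
#' shared by consecutive blocks.  With maximal overlapping (\code{L = n - 1})
#' every sample contributes and \code{M = N - n + 1}; otherwise up to
#' \code{n - L - 1} trailing samples are excluded.
#'
#' @param N Series length.
#' @param n Block size, \code{4 <= n <= N}.
#' @param L Overlap, \code{0 <= L < n}.
#' @return A list of class \code{mfdfa_blocks}: \code{n}, \code{L}, \code{M}
#'   (block count), \code{I} (1-based start indices), \code{excluded_tail}.
#' @examples
#' block_scheme(100, 10, 9)$M   # 91: maximal overlap
#' block_scheme(100, 10, 0)$I   # 1, 11, ..., 91
#' @export
block_scheme <- function(N, n, L) {
  N <- as.integer(N); n <- as.integer(n); L <- as.integer(L)
  if (n < 4L) stop("block size n must be at least 4")
  if (n > N) stop("block size n = ", n, " exceeds series length N = ", N)
  if (L < 0L || L >= n) stop("overlap L must satisfy 0 <= L < n")
  step <- n - L
  M <- (N - n) %/% step + 1L
  I <- step * (seq_len(M) - 1L) + 1L
  tail_len <- N - (M - 1L) * step - n
  structure(
    list(n = n, L = L, M = M, I = I, excluded_tail = tail_len),
    class = "mfdfa_blocks"
  )
}

#' Closed-form sums of integer powers (Faulhaber)
#'
#' \eqn{\sum_{i=1}^n i^V} for \eqn{V = 1..4} without summation, via the
#' product forms n(n+1)/2, n(n+1)(2n+1)/6, [n(n+1)/2]^2 and
#' n(n+1)(2n+1)(3n^2+3n-1)/30, which keep intermediate values integral.
#' These feed the design-matrix moments of the analytic least-squares fit,
#' so every block at a given scale shares the same O(1) constants.
#'
#' @param V Power, integer in 1..4.
#' @param n Upper limit, integer >= 1 (vectorized).
#' @return \eqn{\sum_{i=1}^n i^V}, exact while below 2^53.
#' @examples
#' power_sum(1, 10)  # 55
#' power_sum(3, 4)   # 100
#' @export
power_sum <- function(V, n) {
  if (length(V) != 1L || !(V %in% 1:4)) stop("V must be a single integer in 1..4")
  if (any(n < 0)) stop("n must be >= 0")
  n <- as.numeric(n)
  switch(V,
    n * (n + 1) / 2,
    n * (n + 1) * (2 * n + 1) / 6,
    (n * (n + 1) / 2)^2,
    n * (n + 1) * (2 * n + 1) * (3 * n^2 + 3 * n - 1) / 30
  )
}

#' Sum of powers of n consecutive integers
#'
#' \eqn{\sum_{i=I_k}^{I_k+n-1} i^V} as a difference of two Faulhaber sums.
#'
#' @param V Power, integer in 1..4.
#' @param I_k First integer of the range (>= 1).
#' @param n Number of consecutive integers.
#' @return The range sum.
#' @examples
#' range_power_sum(1, 5, 5)  # 5+6+7+8+9 = 35
#' @export
range_power_sum <- function(V, I_k, n) {
  if (any(I_k < 1)) stop("I_k must be >= 1")
  power_sum(V, I_k + n - 1) - power_sum(V, I_k - 1)
}
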