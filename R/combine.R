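#' Weight of the DFA2 estimate in the combined alpha surface
#'
#' For series in the fractional-Gaussian-noise / fractional-Brownian-motion
#' family, DFA1 is preferable at the shortest scales (second-order detrending
#' overfits small blocks), while at larger scales DFA2 is more stable for
#' negative q, DFA1 for positive q, and their average is best at q = 0.
#' The combined estimate is \eqn{\alpha^w = (1-w_2)\alpha^1 + w_2\alpha^2}
#' with \eqn{w_2 = r(n) \cdot (5-q)/10}, where the scale ramp r(n) is 0 for
#' n < 12, rises linearly to 1 between n = 12 and n = 24, and is 1 beyond —
#' so the weights are linear in q between the calibrated extremes q = -5
#' (pure DFA2 at large n) and q = +5 (pure DFA1), and continuous in n.
#'
#' @param q Moment order(s), calibrated for q in [-5, 5]; values outside are
#'   clamped with a warning.
#' @param n Scale(s), in samples (real-valued allowed).
#' @return w2 in [0, 1], recycled over \code{q} and \code{n}.
#' @examples
#' combination_weight(-5, 18)  # 0.5
#' combination_weight(0, 30)   # 0.5
#' combination_weight(5, 100)  # 0
#' @export
combination_weight <- function(q, n) {
  if (any(q < -5 | q > 5)) {
    warning("q outside the calibrated range [-5, 5]; weight clamped")
    q <- pmin(pmax(q, -5), 5)
  }
  ramp <- pmin(pmax((n - 12) / 12, 0), 1)
  ramp * (5 - q) / 10
}

#' Combine DFA1 and DFA2 alpha surfaces
#'
#' Pointwise weighted average of the two scaling-exponent surfaces with the
#' q- and n-dependent weights of [combination_weight()].  Offered when there
#' is no domain reason to prefer a single detrending order and the dynamics
#' can be assumed fGn/fBm-like.
#'
#' @param alpha1,alpha2 \code{mfdfa_alpha} objects of order 1 and 2 on
#'   identical (q, n_h) grids.
#' @return An \code{mfdfa_alpha} object with \code{order = "weighted"}.
#' @export
combine_surfaces <- function(alpha1, alpha2) {
  stopifnot(inherits(alpha1, "mfdfa_alpha"), inherits(alpha2, "mfdfa_alpha"))
  if (!isTRUE(all.equal(alpha1$q, alpha2$q)) ||
      !isTRUE(all.equal(alpha1$n_h, alpha2$n_h))) {
    stop("alpha surfaces must share identical (q, n_h) grids")
  }
  w2 <- outer(alpha1$q, alpha1$n_h, combination_weight)
  aw <- (1 - w2) * alpha1$alpha + w2 * alpha2$alpha
  # a zero-weight side must not poison the average with its NAs
  aw[w2 == 0] <- alpha1$alpha[w2 == 0]
  aw[w2 == 1] <- alpha2$alpha[w2 == 1]
  structure(list(q = alpha1$q, n_h = alpha1$n_h, alpha = aw, order = "weighted"),
            class = "mfdfa_alpha")
}
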