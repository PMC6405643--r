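# Tiny brute-force oracle, deliberately naive: per-block polynomial fit via
# lm() on the Vandermonde design and plain arithmetic everywhere.  Used to
# freeze expected values for the fast path at desk scale.

naive_block_variances <- function(y, n, L, order) {
  N <- length(y)
  step <- n - L
  M <- (N - n) %/% step + 1L
  sapply(seq_len(M), function(k) {
    I <- step * (k - 1L) + 1L
    z <- y[I:(I + n - 1L)]
    j <- seq_len(n)
    fit <- if (order == 1L) stats::lm(z ~ j) else stats::lm(z ~ j + I(j^2))
    mean(stats::residuals(fit)^2)
  })
}

naive_fq <- function(x, q, n, L_of_n, order, eps = 0) {
  s <- x - mean(x)
  s <- s / sqrt(mean(s^2))
  y <- cumsum(s)
  sapply(n, function(nb) {
    v <- naive_block_variances(y, nb, L_of_n(nb), order)
    keep <- v >= eps
    if (any(q <= 0)) NULL
    sapply(q, function(qq) {
      k <- keep
      if (qq <= 0) k <- k & v > 0
      if (!any(k)) return(NA_real_)
      vv <- v[k]
      if (qq == 0) exp(mean(log(vv)) / 2) else mean(vv^(qq / 2))^(1 / qq)
    })
  })
}

# deterministic small test series
wiggle <- function(n, seed = 42) {
  set.seed(seed)
  stats::rnorm(n) + 0.3 * sin(seq_len(n) / 7)
}
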