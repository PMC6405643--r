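test_that("normalization removes mean and scale and stores the originals", {
  z <- normalize_series(c(1, 2, 3, rep(c(0, 4), 8)))
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$values^2)), 1, tolerance = 1e-12)

  # population SD: [1,2,3]-style values give +/- sqrt(3/2)
  x <- rep(c(1, 2, 3), 6)
  z <- normalize_series(x)
  expect_equal(sort(unique(round(z$values, 6))),
               round(c(-1, 0, 1) / sqrt(2 / 3), 6))
  expect_equal(z$mu_S, 2)
  expect_equal(z$sigma_S, sqrt(2 / 3))

  # affine invariance and identity case
  x <- wiggle(64)
  expect_equal(normalize_series(5 * x + 11)$values, normalize_series(x)$values,
               tolerance = 1e-12)
  u <- normalize_series(x)$values
  expect_equal(normalize_series(u)$values, u, tolerance = 1e-12)

  expect_error(normalize_series(rep(3, 20)), "constant")
  expect_error(normalize_series(rnorm(8)), "too short")
})

test_that("profile is the exact running sum and inverts by differencing", {
  expect_equal(cumulative_profile(c(1, 1, 1)), c(1, 2, 3))
  expect_equal(cumulative_profile(c(1, -1, 1, -1)), c(1, 0, 1, 0))
  s <- wiggle(200)
  y <- cumulative_profile(s)
  expect_identical(diff(y), diff(cumsum(s)))
  expect_identical(y[1], s[1])
})

test_that("block scheme counts, starts and tail follow the overlap rule", {
  b <- block_scheme(100, 10, 9)
  expect_equal(b$M, 91)
  expect_equal(b$I, 1:91)
  expect_equal(b$excluded_tail, 0)

  b <- block_scheme(100, 10, 0)
  expect_equal(b$M, 10)
  expect_equal(b$I, seq(1, 91, by = 10))

  b <- block_scheme(103, 10, 5)
  expect_equal(b$M, 19)
  expect_equal(b$excluded_tail, 3)

  # maximal overlap M = N - n + 1 across a sweep
  for (n in c(4, 7, 16, 50)) {
    expect_equal(block_scheme(200, n, n - 1)$M, 200 - n + 1)
  }

  expect_error(block_scheme(50, 60, 0), "exceeds")
  expect_error(block_scheme(50, 10, 10), "0 <= L < n")
})

test_that("Faulhaber power sums match direct integer summation", {
  expect_identical(power_sum(1, 10), 55)
  expect_identical(power_sum(3, 4), 100)
  expect_identical(power_sum(4, 10), 25333)
  for (V in 1:4) {
    ns <- c(1:20, 97, 512, 1000)
    expect_identical(power_sum(V, ns),
                     sapply(ns, function(n) sum(seq_len(n)^V)),
                     label = paste("V =", V))
  }
  expect_error(power_sum(5, 10), "1..4")
})

test_that("range power sums reduce to Faulhaber differences", {
  expect_identical(range_power_sum(1, 5, 5), 35)
  expect_identical(range_power_sum(2, 1, 10), power_sum(2, 10))
  expect_identical(range_power_sum(4, 3, 2), 337)
})

test_that("segmented prefix store reproduces the direct running sums", {
  y <- cumulative_profile(normalize_series(wiggle(1e4)))
  st <- build_prefix_store(y)
  i <- as.numeric(seq_along(y))
  direct <- list("01" = cumsum(y), "11" = cumsum(i * y),
                 "21" = cumsum(i^2 * y), "02" = cumsum(y^2))
  for (key in names(direct)) {
    V <- as.integer(substr(key, 1, 1)); W <- as.integer(substr(key, 2, 2))
    A <- fastMFDFA:::prefix_running_sum(st, V, W)
    expect_equal(A[-1], direct[[key]], tolerance = 1e-12,
                 label = paste("A", key))
    expect_equal(A[1], 0)
  }
})

test_that("prefix store honours the segment-width option", {
  y <- cumulative_profile(normalize_series(wiggle(300)))
  for (w in c(1L, 7L, 128L, 1024L)) {
    st <- build_prefix_store(y, seg_width = w)
    expect_equal(fastMFDFA:::prefix_running_sum(st, 1, 1)[-1],
                 cumsum(seq_along(y) * y), tolerance = 1e-12)
  }
})

test_that("block moments equal direct block summation", {
  y <- cumulative_profile(normalize_series(wiggle(1e4)))
  st <- build_prefix_store(y)
  i <- as.numeric(seq_along(y))
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(4:500, 1)
    I <- sample(seq_len(length(y) - n + 1L), 1)
    idx <- I:(I + n - 1L)
    expect_equal(block_moment(st, 1, 1, I, n), sum(i[idx] * y[idx]),
                 tolerance = 1e-10)
    expect_equal(block_moment(st, 0, 2, I, n), sum(y[idx]^2),
                 tolerance = 1e-10)
  }
  # I_k = 1 reduces to the plain running sum at n
  expect_equal(block_moment(st, 2, 1, 1L, 50L), sum(i[1:50]^2 * y[1:50]),
               tolerance = 1e-12)
  expect_error(block_moment(st, 1, 1, length(y), 10), "outside")
  expect_error(block_moment(st, 3, 1, 1, 10), "not tracked")
})

test_that("analytic block fits match a generic least-squares solve", {
  j <- 1:20
  expect_equal(fit_block_poly(2 * j + 3, 1), c(a = 3, b = 2), tolerance = 1e-12)
  expect_equal(fit_block_poly(j^2, 2), c(a = 0, b = 0, c = 1), tolerance = 1e-10)

  set.seed(3)
  for (n in c(6, 17, 100)) {
    z <- rnorm(n) + 0.1 * seq_len(n)
    jj <- seq_len(n)
    f1 <- stats::lm(z ~ jj)
    expect_equal(unname(fit_block_poly(z, 1)), unname(coef(f1)),
                 tolerance = 1e-9)
    f2 <- stats::lm(z ~ jj + I(jj^2))
    expect_equal(unname(fit_block_poly(z, 2)), unname(coef(f2)),
                 tolerance = 1e-9)
  }
  expect_error(fit_block_poly(1:2, 1), "degenerate")
  expect_error(fit_block_poly(1:3, 2), "degenerate")
})

test_that("fast residual variance agrees with direct summation and is exact on trends", {
  # exact trends: the analytic form leaves only cancellation noise, and the
  # below-threshold direct recompute removes even that
  expect_lt(residual_variance_fast(5 * (1:30) - 2, 1), 1e-11)
  expect_lt(residual_variance_fast(0.5 * (1:30)^2 - 3 * (1:30) + 1, 2), 1e-11)
  expect_equal(residual_variance_fast(5 * (1:32) - 2, 1, th = 1e-3), 0,
               tolerance = 1e-20)
  set.seed(8)
  for (n in c(10, 100, 1000)) {
    z <- cumsum(rnorm(n))
    for (o in 1:2) {
      jj <- seq_len(n)
      fit <- if (o == 1) stats::lm(z ~ jj) else stats::lm(z ~ jj + I(jj^2))
      direct <- mean(stats::residuals(fit)^2)
      expect_equal(residual_variance_fast(z, o), direct, tolerance = 1e-8)
    }
  }
})

test_that("compiled direct kernel matches the naive lm-based oracle", {
  y <- cumulative_profile(normalize_series(wiggle(400)))
  for (o in 1:2) {
    for (spec in list(c(10, 9), c(16, 0), c(25, 12))) {
      n <- spec[1]; L <- spec[2]
      sch <- block_scheme(length(y), n, L)
      expect_equal(fastMFDFA:::direct_variances_cpp(y, sch$I, n, o),
                   naive_block_variances(y, n, L, o), tolerance = 1e-9,
                   label = paste("order", o, "n", n, "L", L))
    }
  }
})

test_that("default thresholds follow the length rules", {
  th <- default_thresholds(1e4)
  expect_equal(th$th1, 1e-3)
  expect_equal(th$th2, 1)
  expect_equal(default_thresholds(1e6)$th1, 1e-2)
  expect_equal(default_thresholds(1e2)$th2, 1e-2)
  expect_equal(th$eps, 0)
})

test_that("fluctuation function implements the generalized power mean", {
  expect_equal(fluctuation_function(c(1, 4), 2)$F, sqrt((1 + 4) / 2))
  expect_equal(fluctuation_function(c(1, 4), 0)$F, sqrt(2))
  expect_equal(fluctuation_function(c(1, 4), -2)$F, ((1 + 1 / 4) / 2)^(-1 / 2))
  # constant variances: F = sqrt(v) for every q including 0
  for (q in c(-5, -1, 0, 0.5, 2, 5)) {
    expect_equal(fluctuation_function(rep(2.25, 7), q)$F, 1.5,
                 label = paste("q =", q))
  }
  # eps discards uniformly; zero variances drop out at q <= 0
  r <- fluctuation_function(c(0, 1, 4), 0)
  expect_equal(r$retained, 2L)
  expect_equal(r$F, sqrt(2))
  r <- fluctuation_function(c(0, 1, 4), 2)
  expect_equal(r$retained, 3L)
  r <- fluctuation_function(c(1e-9, 1, 4), -2, eps = 1e-6)
  expect_equal(r$retained, 2L)
  r <- fluctuation_function(c(0, 0), -1)
  expect_true(is.na(r$F))
  expect_equal(r$retained, 0L)
})

test_that("F_q(n) surface matches the naive oracle on a small series", {
  x <- wiggle(512)
  q <- c(-3, 0, 2)
  n <- c(8, 16, 32)
  fast <- fq_surface(x, q = q, n = n, orders = 1)
  expected <- naive_fq(x, q, n, function(nb) nb - 1L, 1L)
  expect_equal(unname(fast$F), unname(expected), tolerance = 1e-8)
  fast2 <- fq_surface(x, q = q, n = n, orders = 2)
  expected2 <- naive_fq(x, q, n, function(nb) nb - 1L, 2L)
  expect_equal(unname(fast2$F), unname(expected2), tolerance = 1e-8)
  # non-overlapping blocks too
  fast0 <- fq_surface(x, q = q, n = n, overlap = "none", orders = 1)
  expected0 <- naive_fq(x, q, n, function(nb) 0L, 1L)
  expect_equal(unname(fast0$F), unname(expected0), tolerance = 1e-8)
})

test_that("F_q is non-decreasing in q at every scale (power-mean monotonicity)", {
  for (seed in 1:3) {
    x <- wiggle(1024, seed = seed)
    f <- fq_surface(x, q = seq(-5, 5, by = 0.5), orders = c(1, 2))
    for (s in f) {
      dq <- apply(s$F, 2, diff)
      expect_true(all(dq > -1e-12 | is.na(dq)), label = paste("seed", seed))
    }
  }
})

test_that("surfaces are invariant under positive affine transforms of the input", {
  x <- wiggle(1024)
  f1 <- fq_surface(x, q = c(-2, 0, 2), orders = c(1, 2))
  f2 <- fq_surface(3 * x + 7, q = c(-2, 0, 2), orders = c(1, 2))
  expect_equal(f1$dfa1$F, f2$dfa1$F, tolerance = 1e-10)
  expect_equal(f1$dfa2$F, f2$dfa2$F, tolerance = 1e-10)
})

test_that("polynomial profiles are annihilated exactly by matching detrending order", {
  # series whose profile is an exact straight line
  N <- 256
  prof1 <- 0.37 * (1:N) + 2
  s1 <- c(prof1[1], diff(prof1))
  y <- cumulative_profile(s1)                 # = prof1 by construction
  v <- fastMFDFA:::direct_variances_cpp(y, block_scheme(N, 16, 15)$I, 16L, 1L)
  expect_true(all(abs(v) < 1e-20))
  # quadratic profile, order 2
  prof2 <- 0.01 * (1:N)^2 - 0.2 * (1:N) + 3
  y2 <- c(prof2[1], diff(prof2))
  v2 <- fastMFDFA:::direct_variances_cpp(cumsum(y2), block_scheme(N, 16, 15)$I, 16L, 2L)
  expect_true(all(abs(v2) < 1e-16))
})

test_that("missing cells are reported missing, not zero", {
  # constant increments give an exactly linear profile; all order-1 residuals
  # vanish, so q <= 0 cells are undefined while q > 0 cells are 0.  A truly
  # constant series is rejected upstream, so inject a pre-normalized stub.
  stub <- structure(list(values = rep(1, 64), mu_S = 0, sigma_S = 1, N = 64L),
                    class = "mfdfa_norm")
  f <- fq_surface(stub, q = c(-2, 0, 2), n = c(8, 16), orders = 1)
  expect_true(all(is.na(f$F["-2", ])))
  expect_true(all(is.na(f$F["0", ])))
  expect_true(all(f$F["2", ] == 0))
  expect_true(all(f$retained["-2", ] == 0))
  expect_true(all(f$retained["2", ] > 0))
})
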