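fake_fq <- function(Fmat, q, n, order = 1) {
  structure(list(order = order, q = q, n = n,
                 F = matrix(Fmat, length(q), length(n), dimnames = list(q = q, n = n)),
                 retained = matrix(1L, length(q), length(n)),
                 sigma_S = 1, mu_S = 0, N = max(n) * 4L, overlap = "max",
                 thresholds = list()),
            class = "mfdfa_fq")
}

test_that("log-spline resampling reproduces power laws and the grid spec", {
  n <- unique(round(10^seq(log10(8), 3, by = 1 / 6)))
  Fv <- 0.2 * n^0.75
  fq <- fake_fq(rbind(Fv), q = 2, n = n)
  rs <- resample_log_spline(fq, H = 40)
  expect_length(rs$n_h, 40)
  # equispaced in log to machine precision
  expect_lt(max(abs(diff(diff(log(rs$n_h))))), 1e-12)
  # resampled values still on the power law
  expect_equal(rs$logF[1, ], log(0.2) + 0.75 * log(rs$n_h), tolerance = 1e-9)
  # endpoints span the original scale range
  expect_equal(range(rs$n_h), range(n), tolerance = 1e-12)
})

test_that("resampling a log-equispaced grid at its own resolution is the identity", {
  n <- 2^(3:9)
  Fv <- 3 * n^1.2
  fq <- fake_fq(rbind(Fv), q = 0, n = n)
  rs <- resample_log_spline(fq, H = length(n))
  expect_equal(exp(rs$logF[1, ]), Fv, tolerance = 1e-12)
})

test_that("rows with too few finite cells are reported missing", {
  n <- 2^(3:9)
  Fv <- 3 * n^1.2
  Fm <- rbind(Fv, c(NA, NA, NA, NA, 1, 2, 3))
  fq <- fake_fq(Fm, q = c(2, -2), n = n)
  rs <- resample_log_spline(fq, H = 12)
  expect_true(all(is.finite(rs$logF[1, ])))
  expect_true(all(is.na(rs$logF[2, ])))
})

test_that("derivative formulas are exact on straight lines", {
  x <- seq(log(8), log(4000), length.out = 30)
  f <- 0.75 * x - 1.4
  expect_equal(local_slopes(f, x), rep(0.75, 30), tolerance = 1e-12)
  # and on an affine relabeling of the same grid
  expect_equal(local_slopes(2.5 * x + 3, x), rep(2.5, 30), tolerance = 1e-12)
})

test_that("interior 5-point formula returns the analytic derivative of a quadratic", {
  x <- seq(0, 3, length.out = 21)
  f <- 0.4 * x^2 - x + 2
  s <- local_slopes(f, x)
  interior <- 3:19
  expect_equal(s[interior], 0.8 * x[interior] - 1, tolerance = 1e-10)
})

test_that("edge formulas approach the interior accuracy on smooth curves", {
  # smooth non-polynomial curve: error of the 3-point ends is O(step^2)
  err_at <- function(H) {
    x <- seq(1, 2, length.out = H)
    f <- sin(x)
    s <- local_slopes(f, x)
    abs(s - cos(x))
  }
  e40 <- err_at(40)
  e80 <- err_at(80)
  # halving the step shrinks the end error by ~4x (second order)
  expect_lt(max(e80[c(1, 80)]), max(e40[c(1, 40)]) / 2.5)
  expect_lt(max(e80), 1e-3)
})

test_that("degenerate slope inputs are rejected", {
  expect_error(local_slopes(1:4, 1:4), "at least H = 5")
  expect_error(local_slopes(1:6, log(1:6)), "equispaced")
  expect_error(local_slopes(1:5, 1:6), "equal length")
})

test_that("alpha surface recovers known exponents from synthetic noise", {
  x <- gen_series("white", 2^15, seed = 21)
  f <- fq_surface(x, q = c(0, 2), orders = 1)
  a <- alpha_surface(f)
  band <- a$n_h >= 50 & a$n_h <= 2000
  expect_equal(mean(a$alpha[2, band]), 0.5, tolerance = 0.08)

  xb <- gen_series("brownian", 2^15, seed = 22)
  ab <- alpha_surface(fq_surface(xb, q = c(0, 2), orders = 1))
  expect_equal(mean(ab$alpha[2, band]), 1.5, tolerance = 0.08)
})
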