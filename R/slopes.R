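#' Resample log F_q(n) onto an equispaced log-scale grid
#'
#' The finite-difference derivative formulas require scales equispaced in
#' log n.  Each q-row of the surface is interpolated by a natural cubic
#' spline of log F versus log n and evaluated at H points spaced evenly in
#' log scale across the surface's scale range.  Cells emptied by the EPS
#' rule are dropped before fitting; rows with fewer than 4 finite values are
#' reported missing, and no extrapolation is done outside a row's support.
#'
#' @param fq An \code{mfdfa_fq} object.
#' @param H Number of resampled scales; default from \code{h_per_decade}.
#' @param h_per_decade Resampling density (default 25 per decade).
#' @return List with \code{n_h} (real scales), \code{logF} (q x H matrix of
#'   interpolated log F values, NA where unsupported), \code{q}.
#' @export
resample_log_spline <- function(fq, H = NULL, h_per_decade = 25) {
  stopifnot(inherits(fq, "mfdfa_fq"))
  ln <- log(fq$n)
  if (is.null(H)) {
    H <- max(5L, as.integer(ceiling(h_per_decade * log10(max(fq$n) / min(fq$n)))) + 1L)
  }
  if (H < 5L) stop("H must be at least 5")
  lx <- seq(min(ln), max(ln), length.out = H)
  out <- matrix(NA_real_, length(fq$q), H, dimnames = list(q = fq$q, NULL))
  for (i in seq_along(fq$q)) {
    ok <- is.finite(fq$F[i, ]) & fq$F[i, ] > 0
    if (sum(ok) < 4L) next
    xs <- ln[ok]; ys <- log(fq$F[i, ok])
    sp <- stats::spline(xs, ys, xout = lx, method = "natural")$y
    sp[lx < min(xs) - 1e-12 | lx > max(xs) + 1e-12] <- NA_real_
    out[i, ] <- sp
  }
  list(n_h = exp(lx), logF = out, q = fq$q)
}

#' Local slopes of log F versus log n (5-point derivative)
#'
#' First derivative of log F with respect to log n on an equispaced log
#' grid: the interior uses the 5-point central formula
#' \eqn{[8(f_{h+1}-f_{h-1}) - (f_{h+2}-f_{h-2})] / [3(x_{h+2}-x_{h-2})]},
#' the first/last points one-sided 3-point formulas, and the second and
#' second-to-last points the 3-point central difference.  All formulas are
#' exact for straight lines, so a pure power law returns its exponent at
#' every point.
#'
#' @param logF Numeric vector of log fluctuation values (length H >= 5; NA
#'   runs at the edges are tolerated, slopes there are NA).
#' @param log_n Numeric vector of log scales, equispaced.
#' @return Numeric vector of local slopes, same length.
#' @export
local_slopes <- function(logF, log_n) {
  H <- length(logF)
  if (length(log_n) != H) stop("logF and log_n must have equal length")
  if (H < 5L) stop("need at least H = 5 points")
  d <- diff(log_n)
  if (max(abs(d - d[1])) > 1e-8 * abs(d[1])) stop("log_n must be equispaced")
  fin <- which(is.finite(logF))
  out <- rep(NA_real_, H)
  if (length(fin) < 5L) return(out)
  a <- min(fin); b <- max(fin)
  if (!all(is.finite(logF[a:b]))) {
    # use the longest contiguous finite run
    r <- rle(is.finite(logF))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    a <- starts[best]; b <- ends[best]
    if (b - a + 1L < 5L) return(out)
  }
  f <- logF[a:b]; x <- log_n[a:b]
  m <- length(f)
  s <- rep(NA_real_, m)
  h <- 3:(m - 2)
  s[h] <- (8 * (f[h + 1] - f[h - 1]) - (f[h + 2] - f[h - 2])) /
    (3 * (x[h + 2] - x[h - 2]))
  s[1] <- (-f[3] + 4 * f[2] - 3 * f[1]) / (x[3] - x[1])
  s[2] <- (f[3] - f[1]) / (x[3] - x[1])
  s[m - 1] <- (f[m] - f[m - 2]) / (x[m] - x[m - 2])
  s[m] <- (f[m - 2] - 4 * f[m - 1] + 3 * f[m]) / (x[m] - x[m - 2])
  out[a:b] <- s
  out
}

#' Local scaling-exponent surface alpha(q, n)
#'
#' Combines [resample_log_spline()] and [local_slopes()]: the multifractal
#' multiscale DFA coefficients alpha(q, n_h) as the first derivative of
#' log F_q versus log n.  alpha is about 0.5 for white noise and about 1.5
#' for Brownian motion at every q; dependence of alpha on q reveals
#' multifractality, dependence on n multiscale structure.
#'
#' @param fq An \code{mfdfa_fq} object (or the output of [fq_surface()] for
#'   a single order).
#' @param H,h_per_decade Resampling grid, see [resample_log_spline()].
#' @return Object of class \code{mfdfa_alpha}: list with \code{q},
#'   \code{n_h}, matrix \code{alpha} (q x H), \code{order}.
#' @export
alpha_surface <- function(fq, H = NULL, h_per_decade = 25) {
  rs <- resample_log_spline(fq, H, h_per_decade)
  al <- rs$logF
  lx <- log(rs$n_h)
  for (i in seq_len(nrow(al))) al[i, ] <- local_slopes(rs$logF[i, ], lx)
  structure(list(q = rs$q, n_h = rs$n_h, alpha = al, order = fq$order),
            class = "mfdfa_alpha")
}

#' @export
print.mfdfa_alpha <- function(x, ...) {
  cat("alpha(q, n) surface, order ", format(x$order), ": ",
      length(x$q), " q x ", length(x$n_h), " scales, n in [",
      round(min(x$n_h), 1), ", ", round(max(x$n_h), 1), "]\n", sep = "")
  invisible(x)
}
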