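#' q-order fluctuation value from block variances
#'
#' The q-order fluctuation function is the generalized power mean of the
#' block residual SDs: \eqn{F_q = (\frac1M \sum_k (\sigma^2_k)^{q/2})^{1/q}}
#' for \eqn{q \ne 0} and \eqn{F_0 = \exp(\frac1{2M} \sum_k \ln \sigma^2_k)}.
#' Blocks with \eqn{\sigma^2 < } \code{eps} are discarded before averaging
#' (uniformly for every q), and zero variances — for which the q <= 0 forms
#' are undefined — are additionally discarded when \code{q <= 0}; \code{M}
#' is replaced by the retained count.  Evaluation is done in log space so
#' that strongly negative \code{q} cannot overflow.
#'
#' @param variances Numeric vector of block residual variances (>= 0).
#' @param q Moment order (single real; q = 0 uses the log-mean limit).
#' @param eps Discard threshold (see [default_thresholds()]).
#' @return List with \code{F} (NA if no block survives) and \code{retained}.
#' @examples
#' fluctuation_function(c(1, 4), 2)$F  # sqrt((1 + 8)/2) = 2.1213
#' fluctuation_function(c(1, 4), 0)$F  # sqrt(2)
#' @export
fluctuation_function <- function(variances, q, eps = 0) {
  if (length(q) != 1L || !is.finite(q)) stop("q must be a single finite number")
  keep <- retain_mask(variances, q, eps)
  m <- sum(keep)
  if (m == 0L) return(list(F = NA_real_, retained = 0L))
  v <- variances[keep]
  if (q == 0) {
    f <- exp(mean(log(v)) / 2)
  } else {
    lv <- (q / 2) * log(v)           # log(v) = -Inf (v = 0) only when q > 0
    mx <- max(lv)
    f <- if (!is.finite(mx)) 0 else exp((mx + log(mean(exp(lv - mx)))) / q)
  }
  list(F = f, retained = m)
}

# Shared block-retention rule: sub-eps blocks are dropped for every q;
# zero variances are dropped additionally wherever q <= 0.
retain_mask <- function(variances, q, eps) {
  keep <- variances >= eps
  if (q <= 0) keep <- keep & variances > 0
  keep
}

#' Exponentially spaced integer scale grid
#'
#' @param N Series length.
#' @param n_min,n_max Scale range (defaults 8 and \code{floor(N/4)}).
#' @param per_decade Grid density in scales per decade of \code{n}.
#' @return Increasing integer vector of block sizes.
#' @export
scale_grid <- function(N, n_min = 8L, n_max = NULL, per_decade = 8) {
  if (is.null(n_max)) n_max <- max(n_min, N %/% 4L)
  if (n_min < 4L) stop("n_min must be at least 4")
  if (n_max > N) stop("n_max cannot exceed N")
  ex <- seq(log10(n_min), log10(n_max), by = 1 / per_decade)
  g <- unique(c(round(10^ex), n_max))
  sort(as.integer(g[g >= n_min & g <= n_max]))
}

#' Fluctuation-function surface F_q(n) for DFA1 and DFA2
#'
#' Single-pass computation of the multifractal fluctuation function over a
#' grid of moment orders \code{q} and block sizes \code{n}, for first- and/or
#' second-order detrending.  One segmented prefix store of profile moments is
#' built once and shared by both detrending orders and all scales, so each
#' block costs O(1) regardless of overlap — the algorithm is as fast with
#' maximally overlapped blocks (\code{overlap = "max"}, consecutive blocks
#' sharing n-1 samples) as without.  Maximal overlapping strongly reduces
#' the variance of the F_q(n) estimate, which is what makes derivative-based
#' local slopes usable.
#'
#' @param x Numeric series (raw units; normalized internally), or an
#'   \code{mfdfa_norm} object.
#' @param q Vector of moment orders (default integers -5..5).
#' @param n Integer vector of block sizes; default [scale_grid()].
#' @param overlap \code{"max"} (L = n-1), \code{"none"} (L = 0) or a single
#'   non-negative integer L (clamped to n-1 at scales where n <= L).
#' @param orders Detrending orders to compute: subset of \code{c(1, 2)}.
#' @param n_min,n_max,per_decade Scale-grid parameters when \code{n} is NULL.
#' @param th1,th2 Precision-recompute thresholds; defaults per
#'   [default_thresholds()].
#' @param eps Low-variance discard threshold (default 0).
#' @param seg_width Prefix-store segment width (default 128).
#' @return If one order is requested, an \code{mfdfa_fq} object: list with
#'   \code{order}, \code{q}, \code{n}, matrix \code{F} (q rows, n columns;
#'   normalized-series units), \code{retained} counts, \code{sigma_S},
#'   \code{mu_S}, \code{N}, \code{thresholds}.  If both orders, a named list
#'   \code{list(dfa1 = , dfa2 = )} of such objects.
#' @examples
#' set.seed(1)
#' fq <- fq_surface(rnorm(2048), q = c(-2, 0, 2), orders = 1)
#' fq$F[, 1:4]
#' @export
fq_surface <- function(x, q = -5:5, n = NULL, overlap = "max",
                       orders = c(1L, 2L), n_min = 8L, n_max = NULL,
                       per_decade = 8, th1 = NULL, th2 = NULL, eps = 0,
                       seg_width = 128L) {
  s <- if (inherits(x, "mfdfa_norm")) x else normalize_series(x)
  N <- s$N
  orders <- sort(unique(as.integer(orders)))
  if (!all(orders %in% c(1L, 2L))) stop("orders must be a subset of c(1, 2)")
  if (is.null(n)) n <- scale_grid(N, n_min, n_max, per_decade)
  n <- sort(unique(as.integer(n)))
  if (any(n < 4L) || any(n > N)) stop("scales must lie in [4, N]")
  defs <- default_thresholds(N, eps)
  th <- list(th1 = if (is.null(th1)) defs$th1 else th1,
             th2 = if (is.null(th2)) defs$th2 else th2)

  y <- cumulative_profile(s)
  store <- build_prefix_store(y, seg_width)

  nq <- length(q); nn <- length(n)
  res <- lapply(orders, function(o) {
    list(F = matrix(NA_real_, nq, nn, dimnames = list(q = q, n = n)),
         retained = matrix(0L, nq, nn, dimnames = list(q = q, n = n)))
  })
  names(res) <- paste0("o", orders)

  for (j in seq_along(n)) {
    nb <- n[j]
    L <- overlap_for(overlap, nb)
    sch <- block_scheme(N, nb, L)
    vs <- block_variances_fast(store, y, sch, orders, th)
    for (o in orders) {
      v <- vs[[paste0("v", o)]]
      key <- paste0("o", o)
      for (i in seq_len(nq)) {
        fr <- fluctuation_function(v, q[i], eps)
        res[[key]]$F[i, j] <- fr$F
        res[[key]]$retained[i, j] <- fr$retained
      }
    }
  }

  out <- lapply(orders, function(o) {
    structure(
      list(order = o, q = q, n = n, F = res[[paste0("o", o)]]$F,
           retained = res[[paste0("o", o)]]$retained,
           sigma_S = s$sigma_S, mu_S = s$mu_S, N = N,
           overlap = overlap, thresholds = c(th, list(eps = eps))),
      class = "mfdfa_fq"
    )
  })
  if (length(out) == 1L) out[[1L]] else stats::setNames(out, paste0("dfa", orders))
}

overlap_for <- function(overlap, n) {
  if (identical(overlap, "max")) return(n - 1L)
  if (identical(overlap, "none")) return(0L)
  L <- as.integer(overlap)
  if (is.na(L) || L < 0L) stop("overlap must be 'max', 'none' or a non-negative integer")
  min(L, n - 1L)
}

#' @export
print.mfdfa_fq <- function(x, ...) {
  cat("F_q(n) surface, DFA", x$order, " (", length(x$q), " q x ",
      length(x$n), " scales), N = ", x$N, "\n", sep = "")
  cat("  q in [", min(x$q), ", ", max(x$q), "], n in [", min(x$n), ", ",
      max(x$n), "], overlap = ", format(x$overlap), "\n", sep = "")
  miss <- sum(!is.finite(x$F))
  if (miss) cat("  missing cells:", miss, "\n")
  invisible(x)
}

#' Tidy table of an F_q(n) surface
#'
#' @param x An \code{mfdfa_fq} object.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Long data frame with columns \code{order}, \code{q}, \code{n},
#'   \code{F_normalized}, \code{F_original_units} (F times the original SD),
#'   \code{retained_blocks}.
#' @export
as.data.frame.mfdfa_fq <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    order = x$order,
    q = rep(x$q, times = length(x$n)),
    n = rep(x$n, each = length(x$q)),
    F_normalized = as.vector(x$F),
    F_original_units = as.vector(x$F) * x$sigma_S,
    retained_blocks = as.vector(x$retained)
  )
}
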