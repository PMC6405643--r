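#' Multifractal multiscale DFA of a time series
#'
#' Fits the full scaling description of a univariate series: the q-order
#' fluctuation function F_q(n) by fast maximally-overlapped DFA with first-
#' and second-order detrending in a single pass ([fq_surface()]), the local
#' scaling-exponent surfaces alpha(q, n) as spline-resampled log-log
#' derivatives ([alpha_surface()]), and — when both detrending orders are
#' computed — their weighted combination ([combine_surfaces()]).
#'
#' @param x Numeric series (e.g. beat-by-beat R-R intervals or EEG samples).
#' @param q Moment orders (default integers -5..5; q = 0 handled by the
#'   log-mean form).
#' @param order \code{"both"} (default), \code{1} or \code{2}.
#' @param overlap \code{"max"} (default; consecutive blocks share n-1
#'   samples), \code{"none"}, or an integer overlap L.
#' @param n Explicit integer scale grid, or NULL for [scale_grid()] with
#'   \code{n_min}, \code{n_max}, \code{per_decade}.
#' @param n_min,n_max,per_decade Scale-grid parameters (defaults 8,
#'   \code{N/4}, 8 per decade).
#' @param h_per_decade Density of the resampled slope grid (default 25).
#' @param th1,th2 Precision-recompute thresholds (defaults per
#'   [default_thresholds()]).
#' @param eps Low-variance discard threshold (default 0).
#' @param combine Compute the weighted DFA1/DFA2 combination (default TRUE
#'   when \code{order = "both"}).
#' @param seg_width Prefix-store segment width (advanced; default 128).
#' @return Object of class \code{mfdfa}: list with \code{fq} (list of
#'   \code{mfdfa_fq} per order), \code{alpha} (list of \code{mfdfa_alpha},
#'   including \code{$weighted} when combined), \code{sigma_S}, \code{mu_S},
#'   \code{N}, \code{settings}, \code{call}.  Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{plot}, \code{as.data.frame}.
#' @examples
#' x <- gen_series("white", 4096, seed = 1)
#' fit <- mfdfa(x, q = c(-5, 0, 5))
#' fit
#' round(coef(fit)[, 1:5], 2)   # alpha ~ 0.5 everywhere for white noise
#' @export
mfdfa <- function(x, q = -5:5, order = "both", overlap = "max", n = NULL,
                  n_min = 8L, n_max = NULL, per_decade = 8,
                  h_per_decade = 25, th1 = NULL, th2 = NULL, eps = 0,
                  combine = NULL, seg_width = 128L) {
  cl <- match.call()
  orders <- switch(as.character(order),
                   both = c(1L, 2L), "1" = 1L, "2" = 2L,
                   stop("order must be 'both', 1 or 2"))
  if (is.null(combine)) combine <- length(orders) == 2L
  if (combine && length(orders) != 2L) {
    stop("the weighted combination needs both detrending orders")
  }
  s <- normalize_series(x)
  fq <- fq_surface(s, q = q, n = n, overlap = overlap, orders = orders,
                   n_min = n_min, n_max = n_max, per_decade = per_decade,
                   th1 = th1, th2 = th2, eps = eps, seg_width = seg_width)
  if (inherits(fq, "mfdfa_fq")) fq <- stats::setNames(list(fq), paste0("dfa", orders))
  H <- NULL
  alpha <- lapply(fq, alpha_surface, H = H, h_per_decade = h_per_decade)
  if (combine) alpha$weighted <- combine_surfaces(alpha$dfa1, alpha$dfa2)
  structure(
    list(fq = fq, alpha = alpha, sigma_S = s$sigma_S, mu_S = s$mu_S,
         N = s$N, settings = list(q = q, orders = orders, overlap = overlap,
                                  eps = eps, h_per_decade = h_per_decade),
         call = cl),
    class = "mfdfa"
  )
}

get_alpha <- function(fit, surface = "weighted") {
  key <- switch(as.character(surface),
                weighted = "weighted", "1" = "dfa1", "2" = "dfa2",
                stop("surface must be 'weighted', 1 or 2"))
  a <- fit$alpha[[key]]
  if (is.null(a)) stop("surface '", surface, "' was not computed in this fit")
  a
}

#' @export
print.mfdfa <- function(x, ...) {
  cat("Multifractal multiscale DFA\n")
  cat("  series: N =", x$N, " (mean", signif(x$mu_S, 4),
      ", SD", signif(x$sigma_S, 4), ")\n")
  cat("  orders:", paste(x$settings$orders, collapse = ", "),
      if (!is.null(x$alpha$weighted)) "+ weighted combination", "\n")
  f1 <- x$fq[[1]]
  cat("  q:", length(f1$q), "values in [", min(f1$q), ",", max(f1$q),
      "];  n:", length(f1$n), "scales in [", min(f1$n), ",", max(f1$n),
      "];  overlap:", format(f1$overlap), "\n")
  a <- x$alpha[[length(x$alpha)]]
  iq2 <- which.min(abs(a$q - 2))
  cat("  alpha(q=", a$q[iq2], ") over mid scales: ",
      round(mean(mid_band(a, iq2), na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

mid_band <- function(a, iq) {
  band <- a$n_h >= 10 * min(a$n_h) & a$n_h <= max(a$n_h) / 2
  if (!any(band)) band <- rep(TRUE, length(a$n_h))
  a$alpha[iq, band]
}

#' Scaling exponents of an mfdfa fit
#'
#' @param object An \code{mfdfa} object.
#' @param surface \code{"weighted"} (default if computed, else the first
#'   fitted order), \code{1} or \code{2}.
#' @param ... Ignored.
#' @return The alpha(q, n) matrix (q rows, resampled scales as columns,
#'   scale values in the column names).
#' @export
coef.mfdfa <- function(object, surface = NULL, ...) {
  if (is.null(surface)) {
    surface <- if (!is.null(object$alpha$weighted)) "weighted"
               else object$settings$orders[1]
  }
  a <- get_alpha(object, surface)
  out <- a$alpha
  dimnames(out) <- list(q = a$q, n = signif(a$n_h, 5))
  out
}

#' @export
summary.mfdfa <- function(object, surface = NULL, ...) {
  if (is.null(surface)) {
    surface <- if (!is.null(object$alpha$weighted)) "weighted"
               else object$settings$orders[1]
  }
  a <- get_alpha(object, surface)
  bands <- list(short = c(-Inf, 16), mid = c(16, 1000), long = c(1000, Inf))
  tab <- sapply(bands, function(b) {
    sel <- a$n_h > b[1] & a$n_h <= b[2]
    if (!any(sel)) return(rep(NA_real_, length(a$q)))
    rowMeans(a$alpha[, sel, drop = FALSE], na.rm = TRUE)
  })
  rownames(tab) <- paste0("q=", a$q)
  structure(list(surface = surface, alpha_bands = tab, N = object$N,
                 sigma_S = object$sigma_S, settings = object$settings),
            class = "summary.mfdfa")
}

#' @export
print.summary.mfdfa <- function(x, ...) {
  cat("mfdfa fit (N = ", x$N, "), surface: ", x$surface, "\n", sep = "")
  cat("mean local scaling exponent by scale band (short <= 16 < mid <= 1000 < long):\n")
  print(round(x$alpha_bands, 3))
  invisible(x)
}

#' Tidy long table of an mfdfa fit's fluctuation surfaces
#'
#' @param x An \code{mfdfa} object.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns \code{order}, \code{q}, \code{n},
#'   \code{F_normalized}, \code{F_original_units}, \code{retained_blocks},
#'   stacked over the fitted detrending orders.
#' @export
as.data.frame.mfdfa <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x$fq, as.data.frame))
}

#' Plot an mfdfa fit
#'
#' \code{type = "alpha"} draws the alpha(q, n) surface as a filled image on
#' a log scale axis; \code{type = "fq"} draws the log-log fluctuation
#' functions, one line per q.
#'
#' @param x An \code{mfdfa} object.
#' @param type \code{"alpha"} or \code{"fq"}.
#' @param surface Which alpha surface (see [coef.mfdfa()]).
#' @param order Which detrending order for \code{type = "fq"} (default the
#'   first fitted).
#' @param ... Further arguments passed to [graphics::image()] /
#'   [graphics::matplot()].
#' @return Invisibly, \code{x}.
#' @export
plot.mfdfa <- function(x, type = c("alpha", "fq"), surface = NULL,
                       order = NULL, ...) {
  type <- match.arg(type)
  if (type == "alpha") {
    if (is.null(surface)) {
      surface <- if (!is.null(x$alpha$weighted)) "weighted"
                 else x$settings$orders[1]
    }
    a <- get_alpha(x, surface)
    graphics::image(log10(a$n_h), a$q, t(a$alpha),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "log10 n", ylab = "q",
                    main = paste0("alpha(q, n), ", surface), ...)
  } else {
    if (is.null(order)) order <- x$settings$orders[1]
    f <- x$fq[[paste0("dfa", order)]]
    graphics::matplot(log10(f$n), t(log10(f$F)), type = "l", lty = 1,
                      xlab = "log10 n", ylab = "log10 F_q(n)",
                      main = paste0("F_q(n), DFA", order), ...)
  }
  invisible(x)
}
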