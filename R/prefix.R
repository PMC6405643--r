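#' Segmented prefix sums of profile moments
#'
#' Builds, for each moment pair (V, W) in {(0,1), (1,1), (2,1), (0,2)}, the
#' running sum \eqn{A_{V,W}(i) = \sum_{m \le i} m^V y_m^W}.  A plain running
#' sum over a long series accumulates rounding error because late terms are
#' added to a total of much larger magnitude, and — worse — a block moment
#' taken as the difference of two huge near-equal totals loses most of its
#' significant digits.  The accumulation is therefore split into segments of
#' \code{seg_width} samples (a 129-row-by-Q-column scheme): each moment is
#' stored as its within-segment partial sum plus a chain of per-segment
#' closing totals.  A block moment is then evaluated as (difference of the
#' two within-segment partials) + (difference of the closing-total chain),
#' so for blocks contained in one segment the chain cancels exactly and
#' only segment-scale numbers are ever subtracted.
#'
#' @param p Numeric profile vector (see [cumulative_profile()]).
#' @param seg_width Segment length; 128 by default (advanced option).
#' @return Object of class \code{mfdfa_prefix}: list with \code{partial}
#'   (named list of length-N within-segment running sums), \code{carry}
#'   (named list of cumulative closing totals, index c+1 holds the total of
#'   segments 1..c, first element 0), \code{col} (segment column of each
#'   sample), \code{N}, \code{seg_width}.
#' @export
build_prefix_store <- function(p, seg_width = 128L) {
  if (!is.numeric(p) || length(p) < 1L) stop("profile must be a non-empty numeric vector")
  seg_width <- as.integer(seg_width)
  if (seg_width < 1L) stop("seg_width must be >= 1")
  N <- length(p)
  i <- as.numeric(seq_len(N))
  terms <- list(
    "01" = p,
    "11" = i * p,
    "21" = i * i * p,
    "02" = p * p
  )
  Q <- (N - 1L) %/% seg_width + 1L
  seg <- lapply(terms, function(t) {
    pad <- Q * seg_width - N
    if (pad > 0L) t <- c(t, numeric(pad))
    m <- matrix(t, nrow = seg_width)
    cs <- apply(m, 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = seg_width)
    list(partial = as.vector(cs)[seq_len(N)],
         carry = dd_cumsum(cs[seg_width, ]))
  })
  structure(
    list(partial = lapply(seg, `[[`, "partial"),
         carry = lapply(seg, `[[`, "carry"),
         col = (seq_len(N) - 1L) %/% seg_width + 1L,
         N = N, seg_width = seg_width),
    class = "mfdfa_prefix"
  )
}

# Double-double running sum of the per-segment closing totals: hi + lo
# represent the chained total error-free, so a later difference between two
# chain values recovers the straddled closings to full precision instead of
# the ~1e-16 * |total| floor of a plain double cumsum.  Vectors carry a
# leading 0 (chain before the first segment).
dd_cumsum <- function(x) {
  Q <- length(x)
  hi <- lo <- numeric(Q + 1L)
  s <- 0; e <- 0
  for (k in seq_len(Q)) {
    a <- s; b <- x[k]
    s <- a + b
    bv <- s - a
    e <- e + ((a - (s - bv)) + (b - bv))   # TwoSum residual, accumulated
    hi[k + 1L] <- s
    lo[k + 1L] <- e
  }
  list(hi = hi, lo = lo)
}

# Running sum A_{V,W}(i) for i = 0..N, reconstructed from the segmented
# store (used by tests and by single-point queries).
prefix_running_sum <- function(store, V, W) {
  key <- paste0(V, W)
  cr <- store$carry[[key]]
  c(0, store$partial[[key]] + (cr$hi + cr$lo)[store$col])
}

#' Block moment via segmented prefix-sum difference
#'
#' \eqn{\sum_{i=I_k}^{I_k+n-1} i^V y_i^W = A_{V,W}(I_k+n-1) - A_{V,W}(I_k-1)},
#' evaluated piecewise on the segmented store (within-segment partials and
#' closing-total chain separately) so that short blocks never subtract
#' whole-series magnitudes.
#'
#' @param store An \code{mfdfa_prefix} object.
#' @param V,W Moment powers; (V, W) must be one of (0,1), (1,1), (2,1), (0,2).
#' @param I_k Block start index (vectorized).
#' @param n Block size.
#' @return The block moment(s).
#' @export
block_moment <- function(store, V, W, I_k, n) {
  stopifnot(inherits(store, "mfdfa_prefix"))
  key <- paste0(V, W)
  if (!key %in% names(store$partial)) {
    stop("moment (V=", V, ", W=", W, ") is not tracked by the store")
  }
  if (any(I_k < 1L) || any(I_k + n - 1L > store$N)) {
    stop("block [I_k, I_k+n-1] falls outside the series")
  }
  P <- store$partial[[key]]
  C <- store$carry[[key]]
  e <- I_k + n - 1L
  s <- I_k - 1L                       # left endpoint, may be 0
  Pe <- P[e]
  ce <- store$col[e]
  zero <- s == 0L
  Ps <- ifelse(zero, 0, P[pmax(s, 1L)])
  cs <- ifelse(zero, 1L, store$col[pmax(s, 1L)])
  (Pe - Ps) + ((C$hi[ce] - C$hi[cs]) + (C$lo[ce] - C$lo[cs]))
}
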