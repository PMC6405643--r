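#' Direct-summation reference F_q(n) surface
#'
#' The slow, transparent counterpart of [fq_surface()]: every block moment is
#' summed sample by sample with compensated (Kahan) accumulation in the local
#' block index, the least-squares fit is solved per block, and the residual
#' variance is the directly accumulated sum of squared residuals.  By
#' definition mathematically identical to the fast prefix-sum path; used to
#' measure the numerical error that the prefix-sum differences introduce.
#' Cost is O(M n) per scale, so use it for validation only.
#'
#' @inheritParams fq_surface
#' @return Same structure as [fq_surface()].
#' @export
reference_fq <- function(x, q = -5:5, n = NULL, overlap = "max",
                         orders = c(1L, 2L), n_min = 8L, n_max = NULL,
                         per_decade = 8, eps = 0) {
  s <- if (inherits(x, "mfdfa_norm")) x else normalize_series(x)
  N <- s$N
  if (N > 1e6) warning("reference path on N > 1e6 samples will be very slow")
  orders <- sort(unique(as.integer(orders)))
  if (!all(orders %in% c(1L, 2L))) stop("orders must be a subset of c(1, 2)")
  if (is.null(n)) n <- scale_grid(N, n_min, n_max, per_decade)
  n <- sort(unique(as.integer(n)))
  y <- cumulative_profile(s)

  nq <- length(q); nn <- length(n)
  res <- lapply(orders, function(o) {
    list(F = matrix(NA_real_, nq, nn, dimnames = list(q = q, n = n)),
         retained = matrix(0L, nq, nn, dimnames = list(q = q, n = n)))
  })
  names(res) <- paste0("o", orders)

  for (j in seq_along(n)) {
    nb <- n[j]
    sch <- block_scheme(N, nb, overlap_for(overlap, nb))
    for (o in orders) {
      v <- direct_variances_cpp(y, sch$I, nb, o)
      key <- paste0("o", o)
      for (i in seq_len(nq)) {
        keep <- retain_mask(v, q[i], eps)
        m <- sum(keep)
        res[[key]]$retained[i, j] <- m
        if (m == 0L) next
        vv <- v[keep]
        res[[key]]$F[i, j] <- if (q[i] == 0) exp(mean(log(vv)) / 2)
                              else mean(vv^(q[i] / 2))^(1 / q[i])
      }
    }
  }

  out <- lapply(orders, function(o) {
    structure(
      list(order = o, q = q, n = n, F = res[[paste0("o", o)]]$F,
           retained = res[[paste0("o", o)]]$retained,
           sigma_S = s$sigma_S, mu_S = s$mu_S, N = N,
           overlap = overlap, thresholds = list(eps = eps, reference = TRUE)),
      class = "mfdfa_fq"
    )
  })
  if (length(out) == 1L) out[[1L]] else stats::setNames(out, paste0("dfa", orders))
}

#' Relative error between a fast and a reference fluctuation surface
#'
#' Per-cell \eqn{\epsilon(q, n) = |F^{fast} - F^{ref}| / F^{ref}}; the
#' maximum over cells summarizes the numerical precision of the fast path.
#' Cells where the reference is 0 or missing are excluded (with a warning
#' for zeros).
#'
#' @param F_fast,F_ref \code{mfdfa_fq} objects on identical (q, n) grids,
#'   or plain numeric arrays of equal shape.
#' @return List with \code{eps} (per-cell matrix), \code{max} and the count
#'   of compared cells.
#' @export
relative_error <- function(F_fast, F_ref) {
  a <- if (inherits(F_fast, "mfdfa_fq")) F_fast$F else F_fast
  b <- if (inherits(F_ref, "mfdfa_fq")) F_ref$F else F_ref
  if (inherits(F_fast, "mfdfa_fq") && inherits(F_ref, "mfdfa_fq")) {
    if (!isTRUE(all.equal(F_fast$q, F_ref$q)) ||
        !isTRUE(all.equal(F_fast$n, F_ref$n))) {
      stop("surfaces must share identical (q, n) grids")
    }
  }
  if (!identical(dim(a), dim(b)) && length(a) != length(b)) {
    stop("surfaces have different shapes")
  }
  zero <- is.finite(b) & b == 0
  if (any(zero)) warning(sum(zero), " reference cells are exactly 0; excluded")
  eps <- abs(a - b) / b
  eps[zero | !is.finite(b) | !is.finite(a)] <- NA_real_
  list(eps = eps, max = if (all(is.na(eps))) NA_real_ else max(eps, na.rm = TRUE),
       n_cells = sum(!is.na(eps)))
}
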