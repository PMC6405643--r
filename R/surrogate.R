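#' Fourier-phase-shuffled surrogate series
#'
#' Returns a series with the same discrete-Fourier amplitudes (hence the
#' same power spectrum, autocorrelation and mean) as the input but i.i.d.
#' uniform random phases, subject to conjugate symmetry so the output is
#' real.  The DC component — and the Nyquist component for even N — is kept
#' unchanged.  Phase shuffling destroys nonlinear temporal structure while
#' preserving all linear spectral features, which is what makes it the null
#' model for nonlinearity tests on scaling surfaces.
#'
#' @param x Numeric series, length >= 16.
#' @param seed Optional integer seed for the phase draw.
#' @return Numeric surrogate series of the same length.
#' @export
phase_surrogate <- function(x, seed = NULL) {
  N <- length(x)
  if (N < 16L) stop("series too short for a surrogate: need at least 16 samples")
  if (!is.null(seed)) set.seed(seed)
  X <- stats::fft(x)
  half <- (N - 1L) %/% 2L                 # freely rotatable positive frequencies
  if (half > 0L) {
    idx <- 2L:(half + 1L)
    phi <- stats::runif(half, 0, 2 * pi)
    X[idx] <- Mod(X[idx]) * exp(1i * phi)
    X[N + 2L - idx] <- Conj(X[idx])
  }
  Re(stats::fft(X, inverse = TRUE)) / N
}

#' Two-sided percentile significance map versus a surrogate ensemble
#'
#' For each (q, n) cell, the original series' alpha value is ranked inside
#' the surrogate ensemble; with mid-ranking of ties,
#' \eqn{r = (\#below + 0.5\,\#equal + 0.5)/(N_s + 1)} and the two-sided
#' type-I error probability is \eqn{p = 2 \min(r, 1 - r)}.  A cell is
#' flagged when p falls below \code{flag_level} (0.01 by default, requiring
#' at least 100 surrogates to be reachable).
#'
#' @param alpha_orig \code{mfdfa_alpha} surface of the original series.
#' @param alpha_surr List of \code{mfdfa_alpha} surfaces of the surrogates
#'   (at least 20), all on the grid of \code{alpha_orig}.
#' @param flag_level Display threshold for the \code{flagged} matrix.
#' @return Object of class \code{mfdfa_sig}: list with \code{q}, \code{n_h},
#'   \code{p} (q x H matrix), \code{flagged} (logical), \code{n_surrogates}.
#' @export
significance_map <- function(alpha_orig, alpha_surr, flag_level = 0.01) {
  stopifnot(inherits(alpha_orig, "mfdfa_alpha"))
  Ns <- length(alpha_surr)
  if (Ns < 20L) stop("need at least 20 surrogates for a percentile map")
  for (s in alpha_surr) {
    if (!isTRUE(all.equal(s$q, alpha_orig$q)) ||
        !isTRUE(all.equal(s$n_h, alpha_orig$n_h))) {
      stop("surrogate alpha surfaces must share the original's (q, n_h) grid")
    }
  }
  a0 <- alpha_orig$alpha
  below <- equal <- finite <- array(0L, dim(a0))
  for (s in alpha_surr) {
    as_ <- s$alpha
    ok <- is.finite(as_) & is.finite(a0)
    below <- below + (ok & as_ < a0)
    equal <- equal + (ok & as_ == a0)
    finite <- finite + ok
  }
  r <- (below + 0.5 * equal + 0.5) / (finite + 1)
  p <- 2 * pmin(r, 1 - r)
  p[finite < 20L | !is.finite(a0)] <- NA_real_
  structure(list(q = alpha_orig$q, n_h = alpha_orig$n_h, p = p,
                 flagged = !is.na(p) & p < flag_level,
                 n_surrogates = Ns, flag_level = flag_level),
            class = "mfdfa_sig")
}

#' @export
print.mfdfa_sig <- function(x, ...) {
  nc <- sum(!is.na(x$p))
  cat("surrogate significance map: ", x$n_surrogates, " surrogates, ",
      nc, " cells\n", sep = "")
  cat("  cells with p < ", x$flag_level, ": ", sum(x$flagged), " (",
      round(100 * sum(x$flagged) / max(nc, 1), 1), "%)\n", sep = "")
  invisible(x)
}

#' Surrogate-data nonlinearity test on the alpha(q, n) surface
#'
#' Generates \code{n_surrogates} phase-shuffled copies of the series, runs
#' the full scaling analysis on the original and every surrogate with
#' identical settings, and returns the two-sided percentile significance
#' map of [significance_map()].  Per-surrogate seeds are derived from
#' \code{seed} so the whole test is reproducible.
#'
#' @param x Numeric series.
#' @param n_surrogates Ensemble size (default 100, the smallest allowing
#'   p < 0.01).
#' @param seed Master seed.
#' @param surface Which alpha surface to compare: \code{"weighted"} (default),
#'   \code{1} or \code{2}.
#' @param ... Settings forwarded to [mfdfa()] (grids, thresholds, eps, ...).
#' @return An \code{mfdfa_sig} object, with the original and mean-surrogate
#'   surfaces attached as \code{alpha_orig} and \code{alpha_surr_mean}.
#' @export
surrogate_test <- function(x, n_surrogates = 100L, seed = NULL,
                           surface = "weighted", ...) {
  fit0 <- mfdfa(x, ...)
  a0 <- get_alpha(fit0, surface)
  seeds <- if (is.null(seed)) rep(list(NULL), n_surrogates)
           else as.list(seed + seq_len(n_surrogates))
  asur <- vector("list", n_surrogates)
  for (k in seq_len(n_surrogates)) {
    xs <- phase_surrogate(x, seed = seeds[[k]])
    asur[[k]] <- get_alpha(mfdfa(xs, ...), surface)
  }
  sig <- significance_map(a0, asur)
  amean <- a0
  amean$alpha <- Reduce(`+`, lapply(asur, `[[`, "alpha")) / n_surrogates
  sig$alpha_orig <- a0
  sig$alpha_surr_mean <- amean
  sig
}
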