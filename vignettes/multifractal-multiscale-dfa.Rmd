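---
title: "Multifractal multiscale DFA with maximally overlapped blocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal multiscale DFA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(fastMFDFA)
```

## The estimator

Detrended fluctuation analysis quantifies how the fluctuations of a series'
cumulative profile grow with the size of the window over which they are
measured.  The input series $S_j$, $j = 1..N$, is normalized to zero mean and
unit standard deviation (population convention, divisor $N$),

$$s_j = \frac{S_j - \mu_S}{\sigma_S},$$

and integrated into the profile $y_i = \sum_{j \le i} s_j$.  Normalization is
not required by DFA itself — every scaling exponent reported here is invariant
under positive affine transforms of the input — but it puts the residual
variances of all series on a common absolute scale, which is what makes the
fixed numerical-precision thresholds below meaningful.  Results can always be
restated in original units as $F_q(n)\,\sigma_S$.

At a scale $n$ the profile is cut into $M$ blocks of $n$ samples whose starts
advance by $n - L$, where $L$ is the overlap between consecutive blocks:

$$M = \left\lfloor \frac{N-n}{n-L} \right\rfloor + 1 .$$

With *maximal overlapping*, $L = n - 1$, every sample contributes, $M = N - n
+ 1$, and the variance of the resulting estimator drops enough that local
slopes can be taken by differentiation rather than by regression over wide
windows.  Each block is detrended by a least-squares polynomial of order 1
(DFA$_1$) or 2 (DFA$_2$); $\sigma_n^2(k)$ is the variance of the residuals of
block $k$.  The $q$-order fluctuation function is the generalized power mean

$$F_q(n) = \left( \frac1M \sum_k \left(\sigma_n^2(k)\right)^{q/2}
  \right)^{1/q}, \qquad
  F_0(n) = \exp\!\left( \frac{1}{2M} \sum_k \ln \sigma_n^2(k) \right),$$

with negative $q$ emphasizing the quietest blocks and positive $q$ the most
variable ones.  The local scaling exponent surface is the log-log derivative
$\alpha(q, n) = d \log F_q / d \log n$: $\alpha \approx 0.5$ for white noise,
$\approx 1.5$ for Brownian motion, dependence on $q$ indicates
multifractality and dependence on $n$ multiscale structure.

## Why a fast path is needed, and how it works

Computed naively, maximally overlapped DFA costs $O(Nn)$ per scale (nearly
$N$ blocks, each fit over $n$ points).  The package instead evaluates every
block in $O(1)$ after an $O(N)$ preparation shared by *both* detrending
orders and *all* scales:

* **Design-matrix moments.** Sums of $i^V$ over a block ($V = 1..4$) are
  Faulhaber closed forms, evaluated in integer-preserving product forms
  (`power_sum()`), so all blocks at a scale share a handful of constants.
* **Data moments.** Sums of $i^V y_i^W$ for $(V,W) \in
  \{(0,1),(1,1),(2,1),(0,2)\}$ come from prefix arrays
  $A_{V,W}(i) = \sum_{m \le i} m^V y_m^W$, one subtraction per block.
* **Analytic fit and residual variance.** The normal equations for orders 1
  and 2 have closed-form solutions in those moments, and the residual
  variance expands into moments as well — no per-sample residual pass.

Two index-magnitude problems are addressed explicitly:

* **Local-index shift.** Block moments are rebased from the global sample
  index $i$ to the local index $j = 1..n$ via
  $\sum j\,y = \sum i\,y - (I_k - 1)\sum y$ and
  $\sum j^2 y = \sum i^2 y - 2(I_k-1)\sum i\,y + (I_k-1)^2 \sum y$,
  so the fitted polynomial never mixes terms of wildly different magnitude
  for blocks deep into a long series.
* **Segmented accumulation.** Each prefix array is stored as within-segment
  running sums over segments of 128 samples plus a chain of per-segment
  closing totals (a 129-row scheme).  A block moment is evaluated as
  *(difference of within-segment partials)* + *(difference of the closing
  chain)*; for blocks inside one segment the chain cancels exactly and only
  segment-scale numbers are subtracted.  The closing chain itself is kept in
  compensated double–double form, so the chain difference is accurate at the
  scale of the straddled segments rather than of the whole-series total.
  This last refinement matters: with a plain double chain, the fast/direct
  agreement on a $10^5$-sample white-plus-Brownian series degrades by about
  three orders of magnitude at $n = 10$.

### Precision thresholds and degenerate blocks

Even so, a block whose residual variance is *tiny* can be dominated by
rounding of the prefix differences.  Whenever the analytic variance falls
below a length-dependent threshold — $Th_1 = 10^{-3}$ for $N \le 10^5$, else
$N/10^8$; $Th_2 = 10^{-2}$ for $N \le 10^2$, else $N/10^4$ — the block is
recomputed by direct compensated summation (moments, refit, residuals), which
bounds the error.  The direct value is a sum of squares and hence
non-negative; a negative analytic value that somehow survives is clipped to
zero with a warning (defensive only).

A different problem is a block whose residual variance is *genuinely* almost
zero (an overfit small block, or low-pass-filtered data): it distorts
$F_q$ severely at negative $q$.  Blocks with $\sigma^2 < EPS$ are therefore
discarded, uniformly for every $q$, and the retained count replaces $M$.
The default is $EPS = 0$ (keep everything); $10^{-4}$ of the normalized
dynamics is a reasonable value for filtered biomedical signals.  Exact zeros
are additionally dropped wherever $q \le 0$, where the power mean is
undefined; at $q > 0$ they legitimately contribute zero.  Whether sub-EPS
blocks should also leave the $q = 0$ product is not settled usage; this
package excludes them uniformly so that the retained set does not depend on
$q$'s sign, and reports per-cell retention counts.  A cell with no surviving
blocks is reported missing (`NA`), never as 0.

$F_q$ itself is aggregated in log space (a log-sum-exp), so strongly
negative $q$ cannot overflow; the reference implementation uses the plain
arithmetic form, which doubles as a check that the two forms agree where
both are well-conditioned.

## From $F_q(n)$ to $\alpha(q,n)$

The derivative needs log-equispaced scales.  Each $q$-row of $\log F_q$
versus $\log n$ is interpolated by a *natural cubic spline* — the only
statement made by the derivative approach is "a spline"; the natural
interpolating spline is chosen because it has no smoothing parameter to
tune, noise control being delegated to maximal overlapping — and evaluated
at $H$ points, by default 25 per decade (finer than the default $F$-grid of
8 per decade; both configurable).  Rows with fewer than four finite cells
are reported missing, and no extrapolation is done outside a row's support.

Slopes use the five-point central difference in the interior,

$$\alpha(q, n_h) = \frac{8(\log F_{h+1} - \log F_{h-1}) -
  (\log F_{h+2} - \log F_{h-2})}{3(\log n_{h+2} - \log n_{h-2})},$$

a one-sided three-point formula at the first and last grid points and the
three-point central difference at the second and second-to-last.  All four
formulas are exact on straight lines (a pure power law returns its exponent
at every node, which the tests assert to $10^{-12}$), and the interior
formula is exact through degree-4 polynomials of $\log n$.

## Combining DFA$_1$ and DFA$_2$

Both orders come out of a single pass, which invites combining them.  For
series in the fGn/fBm family, second-order detrending overfits the smallest
blocks, while at larger scales DFA$_2$ is the more stable choice at
$q = -5$, DFA$_1$ at $q = +5$, and their average at $q = 0$.  The weighted
surface is

$$\alpha^w = (1 - w_2)\,\alpha^1 + w_2\,\alpha^2, \qquad
  w_2(q, n) = r(n)\,\frac{5 - q}{10},$$

with $r(n)$ rising linearly from 0 at $n = 12$ to 1 at $n = 24$.  The three
calibrated cases $q \in \{-5, 0, +5\}$ fix the two extremes and the
midpoint; the general-$q$ form above is the linear-in-$q$ interpolation
between them and is continuous in $n$ at both joints.  It is a
reconstruction from those calibrated cases, documented as such.  Outside
$q \in [-5, 5]$ the weight is clamped with a warning, because the scheme
was calibrated only on that range.  The combination is the default surface
when both orders are fitted, but domain reasons (e.g. comparability with
DFA$_1$-based clinical indices at short heart-rate scales) may make a
single order preferable, so `coef()`, `plot()` and `write_surface()` all
accept a surface choice.

```{r combi, echo = TRUE}
round(combination_weight(c(-5, 0, 5), 30), 2)   # DFA2 weight at n = 30
```

## Surrogate testing

Scaling surfaces can reflect either nonlinear dynamics or merely the linear
correlation structure.  The package tests this with Fourier-phase-shuffled
surrogates: same discrete-Fourier amplitudes (hence identical power
spectrum, autocorrelation and mean — preserved to $10^{-10}$ relative, a
tested invariant), i.i.d. uniform phases under conjugate symmetry, DC and
Nyquist kept real.  Each of the $N_s$ surrogates (default 100, the smallest
ensemble for which $p < 0.01$ is achievable) is analyzed with *exactly* the
original's settings; per-cell, the original's value is ranked in the
ensemble with mid-rank ties,

$$r = \frac{\#\{\text{below}\} + 0.5\,\#\{\text{ties}\} + 0.5}{N_s + 1},
\qquad p = 2\min(r, 1 - r),$$

a two-sided type-I error probability that can never be exactly zero (an
original outside all 100 surrogates gets $p \approx 0.0099$).  The rank
convention is the package's own choice; it makes $p = 1$ when the original
ties the whole ensemble.  Per-surrogate seeds are derived from one master
seed.

## The synthetic validation processes

The generators in `gen_series()` define the study conditions under which the
estimator is validated:

| model | construction | role |
|---|---|---|
| `white` | i.i.d. $N(0, 1)$ | $\alpha = 0.5$ reference |
| `brownian` | cumulative sum of white noise | $\alpha = 1.5$ reference |
| `wb` | unit white noise + independent walk with increment variance 0.01986918 | crossover at $f = 10^{-2.5}$, scale $\approx 316$ |
| `ar1` | $x_i = 0.9391014\,x_{i-1} + wn_i$ | low-pass, cut-off 0.01; $\alpha \to 0.5$ at large $n$ |
| `cauchy` | i.i.d. Cauchy(0, 3) | heavy-tailed multifractal stress case |
| `cascade` | 14-level binomial multiplicative cascade, weight 0.25, noise floor $10^{-6} \to U(0, 0.01)$, minus its reversed duplicate | canonical multifractal |

The cascade conserves mass exactly before noise-flooring (its $2^{14}$
values sum to 1, a tested invariant) and is exactly antisymmetric after the
reversal step; independent cascades can be concatenated for longer series.

These processes emulate the *scaling* structure of physiological series —
crossovers, multifractality, heavy tails — but none of their measurement
artifacts: no missing beats or ectopy, no quantization, no nonstationary
mean, no band-pass filtering.  Passing validation here shows the estimator
is computed correctly and recovers known exponents; it does not certify
behaviour on un-edited clinical recordings, whose artifact handling is
deliberately upstream of this package (the readers reject missing values
rather than repairing them).

## Numerical and design choices, collected

* Population SD in the normalization (exponents are invariant; the choice
  only fixes the threshold scale, and is documented so thresholds are
  reproducible).
* Scale grid: exponentially spaced integers, default 8 per decade from
  $n_{\min} = 8$ (avoids overfitting the smallest blocks for both orders)
  to $n_{\max} = N/4$; slope grid 25 per decade.  $q$ defaults to the
  integers $-5..5$; any real $q$ is accepted, $q = 0$ dispatching to the
  log form.
* Segment width 128, exposed as an advanced option.
* Tail handling: when $N - n$ is not a multiple of $n - L$ the trailing
  remainder is excluded (no reversed-series second pass).
* The excluded-block rule, thresholds and EPS are identical in the fast and
  reference paths, so their comparison isolates pure floating-point error.
* No randomness anywhere in the estimator; all stochastic components
  (generators, surrogates) are seedable.
* The model object deliberately has no `predict`/`residuals`/`simulate`
  methods: a scaling surface is a description of a series, not a predictive
  model.

Problem sizes used in the shipped validation: the fast/reference agreement
is asserted at $N = 10^4$ (max relative error $< 10^{-6}$) and $N = 10^5$
(decade scales, all integer $q$, both orders, $< 1\%$; measured values are
around $10^{-5}$ or better); exponent recovery uses ten series of
$N = 2 \times 10^5$ (white and Brownian, tolerance $\pm 0.05$) and ten
AR(1) series of $N = 16{,}384$ (large-scale slope $0.5 \pm 0.1$); the
surrogate machinery is exercised on a $2^{14}$-sample cascade with 100
surrogates.

## Known limitations

* Detrending orders above 2 are out of scope (the analytic expansions and
  thresholds would need extending).
* The weighted combination is calibrated for fGn/fBm-like dynamics and
  $q \in [-5, 5]$; outside that family it is an option, not a
  recommendation.
* `power_sum()` is exact only while results stay below $2^{53}$ (always
  true for the local-index sums used internally, where $n \le N/4$ matters,
  not $N$).
* Very short bands of large scales (few $n_h$ points past a crossover)
  carry visible estimator variance even with maximal overlap — averages
  over such bands, as in the AR(1) check, inherit it.

## A worked example

```{r example}
x <- gen_series("wb", 8192, seed = 42)
fit <- mfdfa(x)
fit
summary(fit)
```

The white/brown crossover is visible as the drift of the mid/long-band
exponents from near 0.5 toward 1.5 as $q$ and the scale band move across
the crossover region.

```{r plots, fig.alt = "alpha surface and fluctuation functions"}
op <- par(mfrow = c(1, 2))
plot(fit, type = "fq")
plot(fit)
par(op)
```
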