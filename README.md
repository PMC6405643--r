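# fastMFDFA

Fast multifractal multiscale detrended fluctuation analysis (DFA) for
univariate physiological time series — beat-by-beat R-R intervals, EEG
traces, or any long series whose fractal structure varies with moment order
and time scale.

## What it computes

DFA integrates a normalized series into its profile
*y<sub>i</sub>* = Σ<sub>j≤i</sub> *s<sub>j</sub>*, detrends blocks of *n*
samples with a polynomial of order 1 (DFA₁) or 2 (DFA₂), and summarizes the
block residual variances σ²<sub>n</sub>(k) by the q-order fluctuation
function

> F<sub>q</sub>(n) = ( (1/M) Σ<sub>k</sub> (σ²<sub>n</sub>(k))<sup>q/2</sup> )<sup>1/q</sup>,  F<sub>0</sub>(n) = exp( (1/2M) Σ<sub>k</sub> ln σ²<sub>n</sub>(k) )

The local scaling exponent α(q, n) = d log F<sub>q</sub> / d log n is ≈ 0.5
for white noise and ≈ 1.5 for Brownian motion; its dependence on q measures
multifractality and on n multiscale structure.

The package's point is doing this with **maximally overlapped blocks**
(consecutive blocks share n−1 samples), which cuts the estimator variance
enough to take α as a derivative — at O(N) cost per scale instead of O(N·n),
via closed-form Faulhaber design moments and segmented prefix sums of
profile moments, with both detrending orders computed in one pass.
Numerical safeguards (local-index shift, 128-sample segmented accumulation,
length-dependent recompute thresholds) keep the fast path within ~10⁻⁵
relative of a direct-summation reference even on 10⁵-sample series.

On top of the core estimator it provides:

* α(q, n) surfaces from natural-cubic-spline resampling and 5-point
  log-log derivatives;
* a weighted DFA₁/DFA₂ combination with weights linear in q and ramped in n;
* Fourier-phase-shuffled surrogate testing of nonlinearity with two-sided
  percentile p-value maps;
* seeded generators for the validation processes (white noise, Brownian
  motion, their superposition, AR(1), Cauchy noise, binomial multiplicative
  cascades);
* a slow, transparent reference implementation for numerical validation;
* readers/writers (plain text / CSV in, tidy TSV out), physical-scale
  conversion (beats → seconds, samples → ms) and a command-line front end
  (`exec/mfdfa`: subcommands `fq`, `alpha`, `surrogate-test`, `simulate`,
  `validate`).

## Worked example

```r
library(fastMFDFA)
x <- gen_series("wb", 8192, seed = 42)   # white noise + calibrated random walk
fit <- mfdfa(x)                          # DFA1 + DFA2 + weighted combination
fit
#> Multifractal multiscale DFA
#>   series: N = 8192  (mean -2.458 , SD 3.637 )
#>   orders: 1, 2 + weighted combination
#>   q: 11 values in [ -5 , 5 ];  n: 21 scales in [ 8 , 2048 ];  overlap: max
#>   alpha(q=2) over mid scales: 1.405
summary(fit)
#> mfdfa fit (N = 8192), surface: weighted
#> mean local scaling exponent by scale band (short <= 16 < mid <= 1000 < long):
#>      short   mid  long
#> q=-5 0.962 1.052 1.630
#> q=-4 0.864 1.060 1.609
#> q=-3 0.782 1.071 1.594
#> q=-2 0.721 1.086 1.582
#> q=-1 0.677 1.109 1.561
#> q=0  0.647 1.140 1.531
#> q=1  0.629 1.175 1.504
#> q=2  0.619 1.210 1.487
#> q=3  0.617 1.241 1.471
#> q=4  0.619 1.267 1.444
#> q=5  0.623 1.290 1.407
```

This series is white noise superposed on a random walk with the spectral
crossover calibrated to scale ≈ 316 samples: the short-scale exponents sit
near the white-noise value 0.5 (pulled up by the walk), and the long-scale
band approaches the Brownian value 1.5 — the drift across bands is the
crossover. `coef(fit)` returns the full α(q, n) matrix, `plot(fit)` the
surface, `as.data.frame(fit)` the tidy F_q(n) table, and
`write_surface(fit$alpha$weighted, "alpha.tsv", unit = "rr", mean_rr = 0.9)`
a TSV on a physical time axis.

A nonlinearity test against 100 phase-shuffled surrogates:

```r
sig <- surrogate_test(x, n_surrogates = 100, seed = 7)
sig   # prints the fraction of (q, n) cells with p < 0.01
```

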