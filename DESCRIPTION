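Package: fastMFDFA
Title: Fast Multifractal Multiscale Detrended Fluctuation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detrended fluctuation analysis (DFA) of physiological time
    series with maximally overlapped blocks, computed by an O(N)-per-scale
    prefix-sum algorithm that returns the q-order fluctuation function
    F_q(n) for first- and second-order detrending simultaneously.  Includes
    numerical-precision safeguards (segmented moment accumulation,
    length-dependent recompute thresholds), local scaling-exponent surfaces
    alpha(q,n) from spline-resampled 5-point log-log derivatives, a weighted
    DFA1/DFA2 combination, Fourier-phase-shuffled surrogate testing of
    nonlinearity, seeded generators for fractal and multifractal validation
    series, and a slow direct-summation reference implementation for
    numerical validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
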