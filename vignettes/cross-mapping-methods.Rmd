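---
title: "Causalized cross-mapping and directed information: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causalized cross-mapping and directed information: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmdi)
```

## The problem

Given two uniformly sampled time series $X$ and $Y$, does $X$ causally
influence $Y$? Linear Granger causality answers by asking whether lags of
$X$ improve a linear autoregressive prediction of $Y$; it fails when the
coupling is deterministic, instantaneous, or nonseparable. State-space
methods answer geometrically: if $X$ drives $Y$, the two variables share an
attractor, and by Takens' theorem the attractor can be reconstructed from
either observable alone via delay embedding. Nearby states on the *shadow
manifold* of $X$ then identify nearby states of $Y$, so $Y$ can be
predicted by *cross-mapping* from $X$'s manifold, and the prediction skill
measures the coupling.

This package implements the causalized variant of convergent cross-mapping
(cCCM) alongside classical CCM, plugin estimators of directed information
(DI), the closed-form bridge that links the two for Gaussian processes, a
multivariate conditional extension, a Granger baseline, a simulation suite,
and a network layer for many-channel causality matrices.

## Cross-mapping, causalized

The shadow manifold of $X$ with embedding dimension $E$ and lag $\tau$ is
the point set
$x(t) = [X(t), X(t-\tau), \dots, X(t-(E-1)\tau)]$ for
$t = 1 + (E-1)\tau, \dots, n$. For each predictable $t$ the $K = E + 1$
nearest neighbours of $x(t)$ (Euclidean metric) supply the simplex
estimate

$$\hat Y(t) = \sum_{i=1}^{K} w_i\, Y(t_i), \qquad
  w_i = \frac{e^{-d_i / d_1}}{\sum_j e^{-d_j / d_1}},$$

with $d_1$ the nearest distance; exact matches ($d_1 = 0$) split the
weight uniformly over all zero-distance neighbours. The causation from
$X$ to $Y$ is the Pearson correlation $\rho$ between $Y$ and $\hat Y$ on
the predicted times.

Classical CCM admits every neighbour except the query point itself, so
future values of $Y$ help predict its present — at odds with the premise
of causal analysis that the future cannot influence the past. The causal
variant restricts the neighbour search to time indices strictly earlier
than the query ($t_i < t$). Two consequences follow and are visible in
simulation: cCCM skill is slightly below CCM skill (a smaller admissible
library), and for periodic signals the two coincide, because the past of a
periodic signal already contains its future.

Numerical conventions, chosen for determinism and reproducibility:

* ties in neighbour distance break toward the **smaller time index**;
* in causal mode prediction starts at the first $t$ with at least
  `min_neighbors` (default $K$) admissible past points — earlier times are
  excluded from the correlation, never zero-filled;
* no Theiler exclusion window beyond $t_i \ne t$ (CCM) or $t_i < t$
  (cCCM);
* $\rho$ is reported **signed**; magnitudes are taken only at the network
  layer, whose formulas are defined on $|\rho|$.

The neighbour search is exhaustive ($O(n^2)$ in the series length), which
is exact and matches the naive loop-and-sort oracle bit-for-bit in the
test suite; the hot loop is compiled (Rcpp), so 100-run Monte-Carlo means
at $n = 1024$ remain cheap.

### Choosing $E$ and $\tau$

The defaults are $E = 5$, $\tau = 1$. Theory asks for $E \ge 2d + 1$ with
$d$ the attractor dimension, often less in practice. For systems with
memory — where $Y(t)$ responds to $X$ at discrete dominant delays — two
conditions govern detectability: the embedding span must exceed the
largest dominant delay ($E\tau > d_{max}$), and each dominant delay must
literally appear among the embedding lags $\{0, \tau, \dots,
(E-1)\tau\}$. `check_memory_coverage()` reports both. The delay-memory
generator `ex8_2` ($Y(t) = 0.8X(t-1) + 0.8X(t-4)$) illustrates the
resulting ordering: $E=3,\tau=1$ misses delay 4 entirely, $E=3,\tau=2$
covers only delay 4, $E=5,\tau=1$ covers both, and the measured skill
increases in the same order. There is no automatic $(E, \tau)$ selection:
the toolkit reports, the analyst chooses. Very large $E$ relative to $n$
degrades the neighbour statistics; a warning is emitted when
$E\tau \ge n/10$.

## Directed information

Directed information accumulates the information the present-and-past of
$X$ carries about each $Y_i$ beyond $Y$'s own past, including the
instantaneous exchange:

$$I(X^n \to Y^n) = \sum_{i=1}^{n} I(X^i; Y_i \mid Y^{i-1}).$$

Full histories are not estimable from finite data, so the estimator
truncates conditioning to the last $m$ samples (default $m = 2$) and pools
empirical frequencies over $i$ under stationarity: per sample,
$\widehat{DI} = \hat H(Y_i \mid Y_{past}) - \hat H(Y_i \mid Y_{past},
X_{i-m..i})$, with plugin entropies in bits and the $0 \log 0 = 0$
convention. The quantizer is explicit and logged (default 8 uniform-range
bins; quantile binning available) because DI's fragility traces directly
to digitization: the number of symbol-context combinations must stay well
below $n$, and the estimator attaches an under-sampling flag (and raises a
warning) when combinations exceed $n/5$. At $n \approx 10^3$ this rule
pushes the practical choice down to 2–4 bins and $m = 1$; the package's
own benchmark runs at $n = 1024$ use 2 bins, $m = 1$, which keeps the
plugin bias on independent pairs below 0.01 bits. No bias correction is
applied by default, keeping the estimator equal to its brute-force
definition; Miller–Madow is available as an option.

Two estimator facts worth knowing:

* The truncated per-sample DI obeys the exact plugin bounds
  $0 \le \widehat{DI} \le \hat I(X_{win}; (Y_i, Y_{past}))$ (chain rule);
  the test suite asserts these on every generator. It is **not** bounded
  by the instantaneous mutual information $\hat I(X_i; Y_i)$ that
  `estimate_mi()` reports — systems with lagged coupling legitimately
  carry more directed information than the instantaneous joint
  distribution shows.
* For temporally iid pairs, DI reduces to instantaneous MI, which is
  symmetric: DI cannot orient purely instantaneous maps such as
  $Y = X^2$, while cross-mapping can (the `ex4` generator).

## The cCCM–DI bridge

For dynamically coupled, jointly Gaussian, stationary ergodic processes,
the average DI per sample approaches Gel'fand's closed form of the
cross-map skill:

$$\bar I_n(X \to Y) \;\approx\; -\tfrac12 \log_2\!\left(1 -
\rho^2_{cCCM}(X \to Y)\right).$$

On finite, quantized, noisy data the realized relation is an affine
distortion, $DI \approx a \cdot [-\tfrac12\log_2(1-\rho^2)] + b$, with
constants absorbing quantization error, finite data size and estimator
error propagation. `fit_bridge()` estimates $(a, b)$ by ordinary least
squares of DI on the transformed predictor (vertical residuals in DI —
the simplest reading of a linear transformation of the closed form;
total-least-squares alternatives were deliberately not used), using
$|\rho|$ since the inversion
$|\rho| = \sqrt{1 - 2^{-2(DI-b)/a}}$ returns a magnitude. The constants
are dataset-specific; the only built-in default is the identity bridge
$(a, b) = (1, 0)$, under which the two maps invert each other to machine
precision. On synthetic coupled AR(1) pairs swept over eight coupling
strengths the log-relationship holds with $r^2 > 0.9$ even though the
fitted slope sits well below 1 — the plugin DI with a small alphabet
underestimates the closed form roughly proportionally, which is exactly
the affine distortion the bridge exists to absorb.

## Multivariate conditional cross-mapping

With channels $\Omega = \{X_1, \dots, X_Q\}$, each source manifold
$M_{X_q}$ yields its own cross-map estimate of a target $X_i$. The
combined prediction is the linear combination of per-manifold estimates
minimizing the error variance; the causality ratio of a source $X_j$ is
the fractional variance reduction it contributes:

$$CR_{X_j \to X_i} = \frac{\mathrm{Var}(e \mid \Omega \setminus \{X_j\})
- \mathrm{Var}(e \mid \Omega)}{\mathrm{Var}(e \mid \Omega \setminus
\{X_j\})}.$$

Design choices where the formulation was open:

* the combination has **no intercept**; target and estimate columns are
  mean-centered on the shared rows first, which makes the intercept-free
  fit well-posed;
* both fits are restricted to **identical rows** (the intersection of
  valid prediction times across all source manifolds), so the variance
  comparison is nested and $0 \le CR \le 1$ holds exactly — the reported
  residual variance is the mean squared residual of the centered fit,
  which makes the nesting inequality exact rather than
  up-to-sampling-noise;
* coefficients are re-estimated for every exclusion, as the two
  minimizations imply;
* coefficients are unconstrained (no nonnegativity);
* with $Q = 2$ the excluded-source model is empty and its variance is
  that of the centered target, extending the ratio meaningfully to the
  bivariate limit.

The ratio is deliberately sensitive to interdependence: duplicating a
genuinely causal source makes either copy's ratio collapse toward zero,
because the other copy absorbs its contribution. This is a feature for
probing redundancy (conditioning on individual channels) and a known
limitation for whole-network conditioning, where rich interdependence
drives all ratios toward zero.

## Simulation generators

`generate_example()` provides twelve seeded benchmark scenarios spanning
the regimes the methods must handle: instantaneous bidirectional Gaussian
coupling (`ex1`), independent noise (`ex2`), quadrature sinusoids
$X=\sin t, Y=\cos t$ on $t = 0, 0.01\pi, \dots, 2\pi$ (`ex3`),
sign-destroying quadratic coupling $Y = X^2$ (`ex4`, where the spread of
plausible sign-destroying maps was resolved in favour of the quadratic),
bidirectionally coupled AR(1) pairs at two coupling strengths (`ex5_*`),
a dominant sinusoid in noise driving a noisy response (`ex6_*`),
diffusively coupled logistic maps (`ex7_*`), and delay-memory systems
(`ex8_1`, `ex8_2`). Each generator attaches its ground-truth causal
structure as metadata, so downstream checks depend only on the declared
truth, not on the particular equations.

Where equations are not pinned down by a printed definition, the
generators are explicit synthetic stand-ins with parameters chosen once:

* `ex1` solves the instantaneous linear system $X = Z_1 + 0.4Y$,
  $Y = 0.8X + Z_2$ ($Z_i$ iid standard normal): jointly Gaussian,
  bidirectional, $X \to Y$ stronger, Pearson correlation high
  ($\approx 0.87$).
* `ex5_*` couple two AR(1) processes ($\phi = 0.5$) through lagged
  cross-terms 0.4/0.2 (`ex5_1`) and 0.8/0.2 (`ex5_2`); the same family,
  swept over the $X \to Y$ coefficient, generates the bridge
  calibration data.
* `ex7_*` use the convex-mixing coupled-map form
  $x' = (1-\beta_{yx}) f_{3.8}(x) + \beta_{yx} f_{3.5}(y)$ (and
  symmetrically for $y$), which is closed on $[0,1]$ for any coupling
  fraction — the subtractive coupling form can escape the unit interval
  and diverge at couplings strong enough for the skill to saturate at
  $n = 1024$. Initial conditions are drawn uniformly from the basin so
  Monte-Carlo runs are exchangeable. Couplings are 0.15/0.05 (`ex7_1`)
  and 0.25/0.10 (`ex7_2`).
* `ex8_*` drive the printed delay equations with an AR(1) input
  ($\phi = 0.5$). The driver's memory matters: with a temporally white
  driver the two partial embeddings ($E=3,\tau=1$ vs $E=3,\tau=2$) are
  statistically exchangeable and could not order the detectability the
  way delay coverage predicts; an autocorrelated driver makes the
  $\tau=2$ embedding strictly more informative, which is the regime the
  delay-coverage analysis describes.

`add_awgn()` injects white Gaussian noise at a stated SNR (signal power =
mean square; noise variance = power$/10^{SNR/10}$). On the coupled
Gaussian pair, the mean cCCM skill falls from $\approx 0.80$ (noise-free)
to $\approx 0.26$ at 0 dB and recovers to within 0.05 of noise-free by
15 dB — noise enlarges neighbour distances and dilutes the simplex
weights, so skill decreases monotonically with noise power.

What the generators deliberately do **not** emulate: hemodynamic
convolution, slow drifts, scanner artefacts, inter-subject variability —
the features that distinguish real BOLD recordings from clean synthetic
couplings. Passing the simulation suite therefore certifies the
estimators' algorithmic behaviour under known ground truth, not their
field performance on fMRI data.

## Granger baseline

`granger_causality()` is textbook bivariate GC: nested OLS fits of $Y$ on
its own $p$ lags versus adding $p$ lags of $X$, compared by F-test
(default $p = 5$, paralleling $E = 5$). Deterministic inputs whose
restricted fit is already essentially exact (relative RSS below
$10^{-12}$), and rank-deficient designs, are reported as *degenerate*
with `significant = FALSE` rather than erroring — noiseless sinusoids are
the canonical case. An exactly collinear unrestricted design (which
arises when $Y$ is a noiseless linear function of $X$'s lags) is likewise
degenerate; an exact unrestricted fit over a non-exact restricted one is
extreme evidence, not degeneracy.

## Network layer

`pairwise_matrix()` evaluates all $Q(Q-1)$ ordered pairs under one
metric, storing $|\rho|$ for the cross-map metrics (all network formulas
are defined on magnitudes; signed values remain available from the
bivariate calls). Failed pairs are masked with a warning, not fatal.
Node significance sums outgoing and incoming magnitudes per node.
Unidirectional pairs are selected by thresholded directional differences:
$\Delta_{cCCM} > 0.15$ (single-metric rule), or
$\Delta_{CCM} > 0.1 \wedge \Delta_{cCCM} > 0.1 \wedge \Delta_{DI} > 0.01$
(three-metric rule); thresholds are overridable, and raising any
threshold can only shrink the selection. When records are short, series
are upsampled by the factor-2 not-a-knot cubic spline
(`spline_upsample()`; a 192-sample record becomes $2 \times 192 - 1 =
383$ samples at half the sampling period) rather than self-concatenated:
`concatenation_demo()` shows that doubling a series plants exact
duplicate delay vectors in the "past" and manufactures causality even
between independent series.

## Numerical and interface choices

* Not-a-knot boundary conditions for the interpolating spline (the
  MATLAB `spline` convention), solved as a banded system; exact on cubic
  polynomials, which the tests assert. Original samples are preserved
  bit-exactly at their stride.
* Missing values are rejected at parse time with the offending row and
  column named; no imputation.
* Monte-Carlo runs use consecutive integer seeds from a base seed; every
  randomized quantity in the package is reproducible from one integer.
* Problem sizes in the shipped checks: series length 1024 (the natural
  201-sample grid for the sinusoid example), 100 Monte-Carlo runs for
  mean skills, $n = 10^5$ for the Gaussian MI check, $n = 8000$ for the
  bridge sweep, 18 channels at $n = 60$ for the matrix-shape check.

## Known limitations

* Exhaustive KNN makes cross-mapping $O(n^2)$; DI is $O(n)$ but far more
  sensitive to quantization and data size.
* cCCM's causal restriction spends the earliest samples as burn-in and
  slows convergence on chaotic systems relative to CCM.
* Near the Nyquist rate, cross-mapping may need far more data to
  converge; at or below it, results are generally not meaningful.
* The conditional causality ratio cannot separate redundant sources; a
  near-zero ratio means "no unique contribution", not "no coupling".
* The affine bridge constants are estimator- and dataset-specific; they
  should be refit per dataset, never transported.
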