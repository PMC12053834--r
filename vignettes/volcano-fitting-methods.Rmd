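---
title: "Methods: piecewise-linear volcano fitting, model selection, and descriptor screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piecewise-linear volcano fitting, model selection, and descriptor screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volcanofit)
```

## The model and its assumptions

Descriptor–activity data in catalysis often follow the Sabatier
pattern: performance improves with binding strength up to an optimum
and deteriorates beyond it. `volcanofit` models this with a continuous
piecewise-linear mean response,

$$\hat y(x) = c + \alpha x + \sum_{i=1}^{B} \beta_i\,(x - \psi_i)\,
  H(x - \psi_i), \qquad B \in \{0, 1, 2\},$$

with Gaussian residuals of constant (or weight-modeled) variance. The
slope of segment $j$ is $\alpha + \sum_{i < j}\beta_i$; continuity is
built into the hinge parameterization, so a one-breakpoint volcano has
a sharp tip at $\psi_1$ and a two-breakpoint fit can bound a plateau
top. Two breakpoints is the ceiling: empirical kinetic tables rarely
exceed a few dozen points, and each additional segment costs two
parameters that such samples cannot support. The model is descriptive —
it asserts correlation, not mechanism.

The assumptions that matter in practice: residuals are independent
across catalysts; the descriptor is measured without (appreciable)
error; and the mean response is genuinely piecewise-linear on the scale
supplied. Curvature that is smooth rather than kinked will still be
approximated, but the breakpoint position then reflects the bend region
rather than a physical transition.

## Fitting: iterative breakpoint refinement

For fixed $B \ge 1$ the fit alternates between a linear solve and a
breakpoint update. At the current $\psi$, the design is augmented with
the working covariates $U_i = (x-\psi_i)H(x-\psi_i)$ and
$V_i = -H(x-\psi_i)$; weighted least squares of $y$ on
$[1, x, U, V]$ yields $\hat\beta_i$ (slope change) and $\hat\gamma_i$
(the $V_i$ coefficient, a first-order measure of how far $\psi_i$ is
from optimal), and the update is
$\psi_i \leftarrow \psi_i + \hat\gamma_i/\hat\beta_i$.

Three safeguards make this reliable on small noisy samples:

* **Coarse-scan initialization.** The RSS profile in $\psi$ has one
  local optimum per inter-point interval, and the raw iteration only
  descends into the basin it starts in. The fitter therefore first
  evaluates a fixed-hinge WLS at every interval midpoint (quantiles,
  24 of them, once the sample exceeds 26 distinct values) and starts
  the refinement from the six lowest-RSS basins (five best pairs plus a
  tertile pair for $B=2$). The scan is deterministic: the same data and
  weights always give the same fit, with no random restarts.
* **Step halving.** The raw update can cycle between two adjacent
  basins. A proposed step is accepted only if the hinge-fit RSS does
  not increase; otherwise the step is halved (up to 12 times), and when
  no downhill move remains the iterate is declared converged — it is a
  local minimum along the working direction.
* **Clamping and merging.** Updates are clamped to
  $[x_{(2)}, x_{(n-1)}]$ so a breakpoint can never escape the observed
  range, and two breakpoints closer than the smallest inter-point gap
  are merged, demoting the fit to fewer breakpoints with a flag.

Convergence is declared when the largest breakpoint shift falls below
`tol * range(x)` with `tol = 1e-4`, within `max_iter = 100` iterations
per start; non-convergence returns the best iterate flagged rather than
an error. The reported model refits at the converged $\psi$ with the
$\gamma$ terms dropped. The Heaviside convention is $H(0) = 1$; it is
irrelevant to predictions (the hinge term vanishes at $\psi$ exactly)
but pins the $V$ covariate and the segment membership of a point
sitting on a breakpoint. If every restart collapses
($\hat\beta \approx 0$, i.e. collinear data), the fitter returns the
degenerate hinge fit whose $\beta \approx 0$ reproduces the straight
line, with an undefined breakpoint SE.

The tests pin this machinery to an exhaustive oracle — a 500-point grid
of candidate breakpoints with a WLS solve at each — and require the
iterative RSS within 1% of the grid optimum across 50 seeded datasets
of 12–30 points (in the measured runs it matches or beats the grid).
An independent cross-check against the CRAN `segmented` implementation
runs in the unit tests as well.

## Model selection and the exact-fit sentinel

Candidates $B = 0, 1, 2$ are compared by
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln(n)$ with $k = 2(B+1)$,
computed on the weighted RSS (the quantity the fit minimizes). The
Gaussian-likelihood form is the natural one for least-squares residuals
and makes the two-parameters-per-segment penalty explicit; the form is
recorded in every report so results are interpretable even if compared
across tools using other conventions. An RSS at rounding-noise level
(below $10^{-12}$ of the weighted total sum of squares) is treated as
an exact fit and scores $-\infty$, so a noiseless kink always beats the
straight line; ties break toward fewer breakpoints.

Feasibility follows a points-per-segment rule: $B$ is attempted only
when $n \ge m(B+1)$ and kept only when every *fitted* segment holds at
least $m$ points, with $m = 5$ (minimal) by default and $m = 10$
(conservative) one flag away. The membership check runs after fitting
because breakpoints move. A nesting guard reruns the larger model from
starts seeded by the smaller model's breakpoints if it ever lands on a
worse RSS than the model it contains.

## Shape taxonomy and false-positive invalidation

Shapes are read off the orientation-adjusted segment slopes. For $B=1$:
rise-then-fall is a sharp volcano, fall-then-rise inverted, otherwise
monotonic. For $B=2$ the plateau rule requires a rising first segment,
a falling third, and a middle slope within `flat_tol` (default 0.1) of
the steeper outer slope in relative magnitude. Two cases the slope
rules leave open were decided as follows:

* $B=0$ "flat": a line is called flat when
  $|s_1|\,\mathrm{sd}(x)/\mathrm{sd}(y) \le$ `flat_tol`. This
  dimensionless slope is invariant to affine rescaling of either axis,
  which keeps the whole classifier scale-free (a property the tests
  enforce).
* $B=2$ without a flat middle: classified by sign pattern — a rise
  followed anywhere by a fall is a sharp volcano with the tip at the
  breakpoint where the slope turns negative; fall-then-rise is
  inverted; a single sign is monotonic.

Independently of slopes, any chosen fit with **unweighted** $R^2 < 0$
is classed `invalid`. $R^2$ is always computed on unweighted residuals
even when the fit was weighted: a weighted fit that tracks only the
trusted points can be worse than the mean on the full data, and that
negative $R^2$ is precisely the evidence that a claimed volcano has no
statistical support. An `orientation = "minimize"` flag sign-flips the
slope reading for lower-is-better metrics (e.g. overpotential) without
mutating the data.

## Peak location and uncertainty

Breakpoint standard errors come from the delta method on the final
working regression, $SE(\hat\psi_i) \approx SE(\hat\gamma_i)/
|\hat\beta_i|$, undefined when $\hat\beta_i \approx 0$. A sharp peak is
reported as $\psi \pm z\,SE(\psi)$ and a plateau as the midpoint
$(\psi_1+\psi_2)/2$ with band $[\psi_1 - z\,SE(\psi_1),\ \psi_2 +
z\,SE(\psi_2)]$. The default $z = 1$ (a ±1 SE band) was chosen as the
least committal visualization of peak uncertainty; it is a setting, not
a confidence statement, and users wanting approximate 95% bands can set
$z = 2$. When the SE is undefined the point estimate is still reported
with the band marked unavailable. The acceptance suite checks the
delta-method SE against a 500-replicate nonparametric bootstrap
(agreement within a factor of 2) and that bands shrink as $n$ grows.

## Weighting noisy low-activity points

Points at the bottom of a volcano plot are often the least trustworthy.
The package maps a single scalar $\lambda$ to per-point weights

$$w_i = \max(\tilde y_i, \mathrm{floor})^{\lambda}, \qquad
  \tilde y_i = \frac{y_i - y_{\min}}{y_{\max} - y_{\min}},$$

with `floor = 0.05`. This realizes "down-weight the bottom of the plot"
with one tunable knob: $\lambda = 0$ is uniform, larger $\lambda$
concentrates the fit on high performers, the floor keeps the worst
point from vanishing entirely, and min–max normalization makes the
weights invariant to affine rescaling of the performance axis. The
functional form is a package design choice (documented here precisely
because other mappings are conceivable); an explicit weight column in
the input always overrides it. Constant performance with $\lambda > 0$
is rejected as degenerate rather than silently unweighted.

## Outlier flagging

Outliers are assessed in the 2-D (descriptor, performance) plane after
standardization to zero mean and unit variance: a
minimum-covariance-determinant (MCD) estimate of location and scatter
(via `MASS::cov.rob`) yields robust Mahalanobis distances, points
beyond the $\chi^2_2$ quantile at $1 - \text{contamination}$ are
candidates, and at most $\lceil \text{contamination} \cdot n \rceil$ of
them — the largest distances — are flagged. The default contamination
of 0.1 reflects the expectation that at most one point in ten of a
curated kinetic table is grossly wrong. Below $n = 7$ the MCD is not
meaningful and a per-axis robust z-score (median/MAD, threshold 3.5)
takes over, labeled as such in the report. The MCD's randomized subset
search is pinned to a fixed internal seed so reports are reproducible;
for the small samples typical here the search is exhaustive anyway, and
a test compares its decisions against a brute-force enumeration of all
half-subsets. Flagged points are reported, never removed — in the
low-data regime an extreme-but-genuine point and an outlier can be
indistinguishable, so removal is the analyst's decision. Note the rule
flags *up to* the cap among points beyond the quantile, so on clean
data with heavy-tailed geometry (e.g. the extreme ends of a volcano)
a few conservative flags are expected and harmless.

## Descriptor augmentation and screening

`augment_features()` expands the pool with products of unordered pairs,
ratios of ordered pairs, squares, and (for strictly positive columns)
square roots and logarithms. Guards keep the candidates well-defined:
ratios are dropped when any denominator is within $10^{-12}$ of zero
relative to the column scale, non-finite candidates are excluded with a
logged reason, and expressions are canonicalized (commutative products
in lexicographic order) and deduplicated. One round of composition is
the default; `depth = 2` additionally applies the unary operators to
the binary results, covering forms like the square root of a ratio at
the cost of a larger, more collinear candidate set. Screening runs the
full selection pipeline per candidate and ranks volcano-shaped
candidates by unweighted $R^2$, ties broken by expression string so a
rerun is byte-identical; non-volcano candidates are listed after,
flagged. Monotone transforms of an informative descriptor (its square
root, logarithm) are near-equivalent predictors and legitimately
crowd the top of the ranking; the planted-signal tests therefore count
success as a top candidate built from the informative column and no
decoy.

## What the synthetic generator does and does not emulate

`generate_volcano()` draws the descriptor uniformly (or equispaced)
over a range, evaluates a known piecewise model, and adds i.i.d.
Gaussian noise; options add replicate means with replicate SDs,
heteroscedastic noise proportional to the response level, gross
downward outliers (default shift $-8$ noise SDs, the typical signature
of a degraded or mismeasured catalyst), and decoy descriptors for
screening tables. Defaults — $n = 25$ points, a sharp volcano of unit
slopes on $x \in [0, 10]$ with its tip at $\psi = 5$, noise SD of 10%
of the response range — mirror the size and signal-to-noise of curated
experimental kinetic tables (roughly 6–36 points). Every draw is
governed by an explicit seed and the generator restores the caller's
RNG state.

What it does not emulate: correlated descriptors, descriptor
measurement error, non-Gaussian heavy-tailed noise, mechanistic
structure linking multiple descriptors, or selection effects in which
catalysts get published. Passing tests on synthetic data therefore
demonstrate correctness of the algorithms under the stated noise model,
not robustness to every pathology of real tables.

## Validation problem sizes

The acceptance suite (and `scripts/acceptance.R`, which recomputes the
same quantities from scratch at a user-supplied seed) uses: 50 seeded
datasets of 12–30 points for the grid-oracle equivalence bound (RSS
ratio ≤ 1.01); 200 simulated volcanoes at $n = 25$ for breakpoint
recovery (median error < 5% of the descriptor range); one $n = 30$
dataset with a 500-replicate bootstrap for SE calibration (factor-2
agreement); 200 pure-noise and 200 strong-kink replicates at $n = 20$
for selection consistency (≥ 80% choose $B=0$ on noise, ≥ 95% choose
$B \ge 1$ on kinks); and 20 planted-descriptor screening tables
(≥ 18/20 recovered). These sizes give stable Monte-Carlo estimates for
each rate while keeping a full run in the order of a minute.

A further benchmark tier fits curated experimental case-study tables
(deposited externally, not shipped here); `run_benchmarks()` consumes
such a deposit from `inst/extdata/benchmark/` with a manifest of column
roles and per-case weighting parameters.

## Known limitations

* At most two breakpoints; discontinuous or curved segments are out of
  scope, as are multidimensional volcanoes and multi-product trends.
* The delta-method SE is a first-order approximation; at very small
  $n$ or weak kinks it can understate the uncertainty a bootstrap
  would show (the factor-2 calibration check bounds, not eliminates,
  this).
* Screening is correlation-only. High-$R^2$ composite descriptors are
  hypotheses for a domain expert, not causal findings, and the package
  computes no descriptor values itself — they must be supplied.
* BIC selection at $n \lesssim 10$ is fragile in principle; the
  points-per-segment rule is the guard, and the package warns below 10
  points.
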