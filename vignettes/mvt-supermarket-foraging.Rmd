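---
title: "Methods: MVT analysis of supermarket foraging surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MVT analysis of supermarket foraging surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the knobs that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations — in particular a structural identifiability problem of the
asymptote that users should understand before trusting point estimates.

## The model

A shopper is treated as a central-place forager and a supermarket as a
single resource patch. Cumulative gain after `T` minutes in the patch is

$$g(T) = A\,(1 - e^{-kT}),$$

strictly increasing, strictly concave, saturating at the asymptote `A`
(Euro) with initial rate `A k` (Euro/min). Diminishing returns here do not
require depletable shelves: a shopping list makes each additional item less
valuable, which produces the same concave shape. The trip currency is the
net gain rate

$$E_{net} = \frac{g(T)}{T - t}, \qquad t \le 0,$$

where `t` is the signed round-trip travel time: travel is placed on the
negative time axis so that `T - t` is the total time budget. For fixed `t`
the rate is maximised exactly where the tangent to the gain curve passes
through `(t, 0)`; at that point the net rate equals the marginal rate
`g'(T)`. The tangent condition can be read in both directions:

* `predict_travel_time()` gives `t = T - g(T)/g'(T) = T - (e^{kT}-1)/k`,
  which is negative for every `T > 0` and does not involve `A`;
* `solve_residence_time()` inverts it by solving `e^{kT} = k(T - t) + 1`.

The survey data never say which direction is causal — whether shoppers
chose `T` given their travel time or vice versa — so the package exposes
both and the pipeline uses each where the corresponding hypothesis needs
it: the gain fit treats `(T, g)` pairs as data, the travel evaluation
derives `t` from the fitted curve.

### Numerical inversion

`solve_residence_time()` works on the logarithmic form
`T = \log(1 + k(T - t))/k`, whose residual is expressed in minutes and
therefore converts directly into an error on `T` (the raw exponential
residual does not: its scale varies over fourteen orders of magnitude
across the admissible `(k, T)` box). The root is unique because the
residual is increasing with a non-positive value at `T = 0`. A bracketed
Newton iteration (bisection fallback, bracket expanded geometrically until
sign change) converges to machine precision; the round-trip identity
`solve(predict(T)) = T` holds to ~1e-13 over `k` in [0.005, 1] and `T` up
to 200 min, and the test suite asserts 1e-8.

## The synthetic survey generator

`simulate_foragers()` is the generative mirror of the analysis model. Per
record: a true round-trip travel time is drawn (default log-normal with
median 8 min, truncated to [2, 20] min — walking distances, where
reported round-trip totals plausibly stay under 20 min), the residence time
is the MVT optimum for that travel time under the common curve
(`A = 60` Euro, `k = 0.08`/min), and the gain is the curve value. Reports
are the truth plus independent Gaussian error on each axis
(`sigma_T = sigma_t = 2` min, `sigma_g = 5` Euro), rounded to survey
granularity (1 min, 0.50 Euro) and floored at half a rounding unit.
Context attributes are independent mixtures: the three filter flags have
probabilities 0.8, 0.65 and 0.62, chosen so their product (0.322)
reproduces the subset fraction of the survey setting the generator
emulates (61 walk-in home-round-trip regulars out of 190 complete
interviews); the demographic mixtures follow that sample's composition. Each of the three key
fields is independently blanked with probability 0.02, matching the
observed exclusion rate of about 2%.

The additive, isotropic Gaussian reporting error is an assumption, not a
finding — it is the error model under which orthogonal residuals are the
natural objective. The generator does not emulate: heteroscedastic
reporting (people round long durations more coarsely), correlation between
reporting errors and trip length, within-store micro-patch structure, or
any behavioural deviation from optimality. Passing tests therefore show
that the pipeline recovers its own generative model, not that real
shoppers obey the MVT.

An alternative `curve_shape = "plateau"` generates from a linear-until-
cutoff feedback curve (`plateau_gain()`): gain accrues at a constant rate
until the patch's useful content is exhausted. For that shape the tangent
optimum is the corner itself regardless of travel time, so residence times
are the corner plus behavioural jitter (SD 2 min). It exists to probe how
the exponential fit degrades under shape misspecification.

## Preprocessing

A record enters the analysis only if gain, travel time and residence time
are all present; the subset filters then keep shoppers who mainly shop at
the surveyed patch, travelled home-to-patch-and-back, and came on foot.
Filters are applied in that fixed order purely so attrition reports are
reproducible; the subset itself is order-independent, and both operations
are idempotent. The category cut-points (shopping frequency `<1`, `1-2`,
`3-4`, `5+` per week; household `1`, `2`, `>2`; age `18-29`, `30-49`,
`50+`) are documented, configurable defaults; surveys of this kind form
such categories from free-form answers without a canonical set of bins. Frequency reports are parsed
from free text; range answers such as "3 or 4 times a week" take the
midpoint. Age enters inferential comparisons through a median split (ties
at the median go low), not through the dummy-coding bins. A self-reported
distance column, if present, is dropped.

## Clustering

Two exploratory agglomerative analyses, both complete linkage: Jaccard
distance on the 0/1 dummy variables (socioeconomic structure) and
Euclidean distance on the raw numeric trip variables. The numeric
variables are deliberately *not* standardised by default — minutes and
Euro are kept in their native units, so the dendrogram reflects the
variables as reported — and `standardize = TRUE` is
available for sensitivity analysis. A pair of all-zero dummy rows has
Jaccard distance 0 by definition (identical absence profiles) and is
flagged. The cluster count is suggested by the sharpest bend of the scree
series of merge heights: the `kappa` maximising the discrete second
difference, ties to the smallest `kappa`; a perfectly linear series has no
bend and is flagged rather than silently resolved, and the full series is
always returned so a human can overrule the automation. Agglomeration
itself is `stats::hclust`, cross-checked in the tests against hand
agglomeration and a union-find reconstruction of cut partitions.

## Orthogonal-distance regression

Both coordinates of a `(T, g)` pair are estimates by the same person, so
vertical least squares attributes all error to the gain axis and biases
the curve; the package instead minimises the summed squared Euclidean
distances to the curve. The implementation is nested:

* **inner problem** — for each observation, the footpoint (nearest curve
  point) minimises `(T - T_0)^2 + (g(T) - g_0)^2`. Since the minimal
  distance cannot exceed the vertical residual `v`, the footpoint lies in
  `[max(0, T_0 - v), T_0 + v]`; a 33-point scan of that bracket guards
  against multiple local minima on strongly curved instances, 45
  golden-section steps shrink the best cell, and three safeguarded Newton
  steps on the stationarity condition polish the result. Footpoints match
  a dense-sampling oracle to 1e-6.
* **outer problem** — Nelder-Mead over `(\log A, \log k)` (positivity for
  free), relative objective tolerance 1e-10, at most 500 iterations, with
  slightly coarser inner iteration counts for speed, followed by a
  restart at full precision. Starting values are `A_0 = 1.1 \max g` and
  `k_0 = \bar g /(A_0 \bar T)` clipped to `[10^{-4}, 10]`.

Residual statistics use `n - 2` degrees of freedom (two fitted
parameters): `s^2 = \sum ||D||^2/(n-2)`, `se = \sqrt{s^2}`. The same
`n - 2` convention is used for the travel-time residuals; it is a
convention, not a theorem, and both the objective and the raw residual
table are returned so any other convention can be recomputed.

### Scale dependence and the asymptote identifiability limit

Orthogonal distance adds minutes and Euro in one metric, so the fit is not
equivariant to rescaling either axis; a regression test pins this. The
default keeps raw units, matching standard practice for this analysis;
`standardize = TRUE` fits on unit-variance axes and maps back.

The consequence users must know: when the data cover only short residence
times (here `kT` up to about 1.4 at the generator defaults) *and*
reporting noise is substantial, the raw-unit orthogonal objective has no
interior minimum in `(A, k)`. The data cloud's slope is 2–3 Euro/min, and
a steep near-linear curve (`A` huge, `k` tiny, `A k` fixed) shelters
residuals from the distance metric better than the true concave curve, so
the profile of the objective decreases monotonically toward the degenerate
line limit. The estimate of `A` then diverges while `A k` (the initial
rate) and the fitted curve over the observed range remain sensible. This
is a structural property of unweighted orthogonal fitting near the linear
regime, not an optimiser failure — the acceptance script measures it
directly (parameter recovery at default noise), recovery is excellent at
low noise (the suite asserts 1e-6 relative on noise-free data), and
standardisation softens but does not remove it. Diagnosing it is easy:
`glance()` shows the runaway `A_hat`, and the travel-time evaluation
collapses toward zero predicted travel. Collecting longer residence times
or reducing reporting error are the remedies; per-axis error weighting is
deliberately out of scope.

## Diagnostics and tests

* **Observed-versus-predicted bias**: OLS of observed on predicted; under
  an unbiased model intercept 0, slope 1. The intercept is the headline
  bias indicator.
* **Q–Q against chi-square(2)**: squared residual lengths are compared to
  a chi-square reference with two degrees of freedom. Chi-square(2) is the
  exponential law with mean 2 (`quantile -2 log(1-p)`). The residuals'
  scale is arbitrary, so by default the empirical values are rescaled by
  `mean/2` to match the reference mean — the study did not state its
  scaling, and an unscaled variant is available. Plotting positions are
  `(i - 0.5)/n` by default with Blom positions by flag. Whether a 2-df
  chi-square is the *right* reference for squared distances to a smooth
  curve is debatable (locally the distance is one-dimensional); the
  package implements the comparison as specified and leaves the judgement
  to the reader. Histograms use Freedman–Diaconis bins.
* **Paired t** (observed vs predicted, two-tailed, `df = n - 1`) and
  **Welch t** (Satterthwaite df) wrap `stats::t.test`, with explicit
  zero-variance flags instead of errors. No multiple-testing correction
  is applied, matching the exploratory character of these comparisons.
* **Travel-time evaluation**: predictions use only `k_hat` and each
  record's residence time (`A` cancels); reported round-trip times are
  negated onto the signed convention, and residuals are vertical in the
  travel direction — the prediction target — rather than orthogonal. A
  switch compares absolute instead of signed times.

## Pipeline and reproducibility

`run_mvt_pipeline()` takes exactly one input source (records, CSV, or a
generator config), applies exclusion, categorisation, optional clustering
and filtering, then fit, diagnostics, travel evaluation and the
exploratory Welch comparisons, and returns a flat machine-readable
summary; `write_pipeline_bundle()` serialises it. One integer seed drives
all randomness, and an identical config plus seed yields a byte-identical
summary (asserted in the tests).

The calibration studies run at the study's own design points: n = 61
records per replicate, 200 replicates for parameter recovery, 1,000 for
the paired-t calibration, 10,000 draws for the Q–Q null — sizes chosen so
each property is measured with sampling error well inside its acceptance
band. The paired-t calibration uses predictions from the true generator
curve at the latent residence times, so the test's null holds exactly and
the measured rejection rate isolates the calibration of the testing stage
itself; predictions at noisy residence times would fold in a small
concavity bias, and predictions from a refitted curve are conservative by
construction, since fitting centres the residuals being tested.

## Known limitations

* The asymptote identifiability limit described above: at the default
  reporting-noise level, point estimates of `A` (and hence `k`
  separately) from short-trip data are unreliable; `A k` and fitted
  values over the observed range are the robust quantities.
* Orthogonal distance assumes comparable error on both axes; the package
  neither estimates nor weights per-axis error variances.
* The generator's optimality assumption (every shopper sits exactly at
  the tangent point before noise) is stronger than any claim the analysis
  makes about real shoppers.
* Cluster analyses are exploratory; the automated elbow is a suggestion,
  not an inference.
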