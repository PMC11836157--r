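# mvtforage

Marginal-value-theorem analysis of supermarket foraging surveys.

`mvtforage` treats a grocery shopper as a central-place forager and a
supermarket as a resource patch. It implements the complete analysis
pipeline for survey records of shopping trips — reported round-trip travel
time, time spent in the store, and money spent — under the marginal value
theorem (MVT), together with a synthetic survey generator so that every
stage can be exercised and calibrated without field data. It is aimed at
behavioural ecologists and consumer researchers who want to fit
optimal-foraging models to self-reported trip data.

## The model

Cumulative gain in the patch follows an asymptotic exponential curve

```
g(T) = A (1 - exp(-k T))
```

where `T` is patch residence time (minutes), `A` the maximum attainable
gain (Euro), and `k` the initial gain-rate parameter (1/min). The net gain
rate of a trip is `E_net = g(T) / (T - t)` with the signed travel time
`t <= 0` (travel is plotted on the negative time axis). For a fixed travel
time, `E_net` is maximised where the tangent to the gain curve passes
through `(t, 0)`, giving the two directions the package solves in closed
and iterative form:

* travel time implied by an optimal residence time:
  `t = T - g(T)/g'(T) = T - (exp(kT) - 1)/k` (`predict_travel_time()`), and
* optimal residence time implied by a travel time: the root of
  `exp(kT) = k (T - t) + 1` (`solve_residence_time()`).

Because both residence time and gain are *self-reported estimates*, the
curve is fitted by nonlinear **orthogonal-distance regression**
(`fit_gain_odr()`): `(A, k)` minimise the summed squared Euclidean
distances `||D||` from the observed points to the curve, the
errors-in-variables analogue of least squares. The surrounding pipeline
applies the survey's exclusion rule and applicability filters, runs the two
exploratory hierarchical cluster analyses (Jaccard/complete linkage on
dummy-coded context variables; Euclidean/complete linkage on the numeric
trip variables) with elbow-based cluster-count selection, computes residual
diagnostics (chi-square(2) Q–Q of squared orthogonal residuals,
observed-versus-predicted bias regression), evaluates travel-time
predictions, and reports paired and Welch t tests.

## Worked example

Closed-form pieces first: for a curve with `A = 50` Euro and `k = 0.1`/min,

```r
library(mvtforage)
crv <- gain_curve(A = 50, k = 0.1)
gain(crv, 10)                      # 31.60603  Euro gained after 10 min
predict_travel_time(crv, 10)       # -7.182818 min: 10 min in the patch is
                                   # optimal for a ~7.2 min round trip
solve_residence_time(crv, -7.182818)  # 10 — the inverse direction
```

A full pipeline run on a simulated survey of 194 interviews (the
generator's defaults mirror a city-centre supermarket study: a common gain
curve with `A = 60`, `k = 0.08`, reporting noise on both axes, rounded
answers, and filterable context attributes):

```r
run <- run_mvt_pipeline(config = sim_config(n = 194), seed = 2024)
run
#> MVT survey pipeline run
#>   records: 194 in, 13 excluded incomplete, subset n = 60
#>   gain fit: A_hat = 13566410096.162, k_hat = 0.0000, se_resid = 2.703
#>   travel:   se_resid = 9.314, paired t = -15.949 (p = 0.000)
```

Thirteen interviews missing a key field are excluded; the three filters
(mainly shops here, home round trip, by foot) leave a subset of 60. The
wild `A_hat` is not a bug: at the default reporting-noise level the
asymptote is barely identified by trips this short, and the raw-unit
orthogonal objective then prefers an ever-steeper near-linear curve — the
same instability the diagnostics are designed to expose (see the methods
vignette). With more precise reports the same pipeline recovers the
generator:

```r
cfg <- sim_config(n = 194, sigma_T = 1, sigma_t = 1, sigma_g = 2)
run2 <- run_mvt_pipeline(config = cfg, seed = 2024)
run2
#> MVT survey pipeline run
#>   records: 194 in, 13 excluded incomplete, subset n = 60
#>   gain fit: A_hat = 58.889, k_hat = 0.0828, se_resid = 1.383
#>   travel:   se_resid = 2.330, paired t = 3.264 (p = 0.002)
```

`A_hat = 58.9` and `k_hat = 0.083` sit next to the generating values
(60, 0.08); `se_resid` is the root of `sum(||D||^2)/(n - 2)`. Each stage is
also available on its own and returns tibbles that chain with the pipe:

```r
recs   <- simulate_foragers(sim_config(n = 120, seed = 1))
subset <- exclude_incomplete(recs)$kept |> select_mvt_subset()
fit    <- fit_gain_odr(subset$subset)
glance(fit)          # one-row model summary
augment(fit)         # per-record footpoints and orthogonal residuals
autoplot(fit)        # data, fitted curve, linear comparison
diagnose_fit(fit)    # bias regression, Q-Q pairs, paired t test
```

Field data are read with `read_survey("trips.csv")` and passed to
`run_mvt_pipeline(csv = ...)` or `run_mvt_pipeline(records = ...)`.

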