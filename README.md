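# aalkit

Behavioral analytics for smart-home sensor event streams, aimed at
ambient-assisted-living (AAL) monitoring of older adults living alone.
Simple home sensors — bed, chair and toilet presence, door and fridge
contacts, PIR motion, appliance power meters — log sparse event streams.
`aalkit` turns those streams into interpretable, statistically defensible
statements a caregiver can act on: *time in bed has increased by about
three hours over the period*, *late-morning activity changed significantly
between these two months*, *this user's days fall into five recurring
habit patterns*.

The package covers the full cold path of such a monitoring service, plus
the hot-path pilot-management rules and a household simulator that
provides ground truth for every stage:

| Stage | What it does |
|---|---|
| Event model | Table-schema event logs (CSV/JSONL), validation, 1-min resampled **signature matrices**, daily aggregates |
| BEM | **Behavior explanatory models**: per-quantity GLM pools (bias / linear trend / weekend), AIC selection, IQR and residual outlier screens, rolling windows, daily feature vectors, user discrimination and one-class anomaly detection |
| SP | **Sensor profiles**: per-30-min-bin activation estimates with percentile-bootstrap CIs; two-period comparison by permutation or parametric tests under Holm–Bonferroni FWER control |
| MHC | **Multivariate habits clustering**: GRU or 1-D convolutional autoencoders (built in, with analytic backprop) embed binarized daily matrices; mean-shift/k-means/spectral clustering, prototypes, silhouette and top-5 coverage vs a raw-concatenation baseline |
| Stream rules | Low battery, missing keep-alives, prolonged states — batch replay with one alert per ongoing condition |
| Simulator | Inhomogeneous-Poisson and session-based single-occupant home with diurnal structure, weekend effects, trends, changepoints, outlier days, keep-alives and battery decay |

## The statistics at the core

**Model selection.** For a daily quantity \(y_d\) (hours in bed, toilet
counts, ...) a pool of GLMs over feature subsets {bias}, {bias, trend},
{bias, weekend}, {bias, trend, weekend} is fitted (least squares for
real-valued quantities; Poisson with a negative-binomial refit under
overdispersion for counts) and the model minimizing

> AIC = 2k − 2 ln L

is selected. The trend covariate is scaled to [0, 1] over the window, so
its coefficient reads directly as the *total change over the window*.

**Change detection.** For one sensor, day-level statistics per
time-of-day bin (fraction of time active, or activation indicator) are
compared between two periods with a permutation test per bin; the 48
p-values of the comparison are adjusted by the Holm–Bonferroni step-down,
controlling the family-wise error rate.

**Habit embedding.** Daily 48 × sensors binary matrices are compressed by
an autoencoder trained under binary log loss,
\(L = -\tfrac1N \sum_n [y_n \log \hat y_n + (1-y_n)\log(1-\hat y_n)]\),
with either a GRU encoder
(update gate \(z_t\), reset gate \(r_t\), state
\(h_t = (1-z_t)\circ h_{t-1} + z_t \circ \tanh(W_h x_t + U_h(r_t \circ h_{t-1}) + b_h)\))
or a Conv1D encoder (ReLU convolutions along time with max-pooling).
Days are clustered in the latent space; prototypes are reported back in
the original sensor space.

## Worked example

Simulate a 90-day home whose bed use drifts upward by ~2.9 h over the
window, resample, and ask the BEM stage what happened:

```r
library(aalkit)
sc <- default_home_scenario(days = 90, seed = 1)
sc <- scenario_spec(days = sc$days, routines = sc$routines,
                    trend = list(sensor_id = "bed", total_change = 2.9),
                    seed = sc$seed)
log   <- simulate_household(sc)
specs <- attr(log, "specs")
sig   <- resample_to_signature(log, specs, bin_width = 60)
bed   <- subset(daily_aggregate(sig, log, specs),
                sensor_id == "bed" & !partial)
fit_pool(bed$active_hours, bed$date, family = "gaussian",
         quantity_id = "bed_hours")
```

```
<bem_result> bed_hours best: {bias, linear_trend, weekend} [gaussian], AIC 271.05 (pool of 4)
  coefficients: bias=9.699, linear_trend=2.384, weekend=-0.4709
  total change over window: 2.384 (per day: 0.0274)
  outliers: 1 pre-filtered, 0 residual-flagged
```

The selected model carries a linear-trend term whose coefficient is the
estimated total change (+2.4 h against the +2.9 h planted on session
durations; calendar-day attribution of cross-midnight sleep absorbs part
of it), the bias is the average nightly bed time at the window start, and
one grossly deviant day was screened out before fitting. A comparison of
two equal periods of the same simulation correctly finds nothing:

```r
db  <- daily_bin_stats(sig, "toilet", specs)
compare_periods(db[1:20, ], db[71:90, ], sensor_id = "toilet")
#> <profile_comparison> toilet 48 bins, 20 vs 20 days, permutation test
#>   no significant bins at alpha = 0.05
```

A command-line front end over the same functions ships in
`inst/cli/aalkit.R` (subcommands `simulate`, `resample`, `profile`,
`compare`, `bem`, `rules`, `cluster`); small demo inputs, all synthetic
and generated by the simulator, are under `inst/extdata/`.

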