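---
title: "Methods and design notes for aalkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for aalkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aalkit` analyzes event streams from sparse smart-home sensors to surface
behavioral signals relevant to the care of older adults living alone.
This vignette is the package's own account of the methods: the models and
their assumptions, the parameters that matter, the numerical conventions,
the design choices that were genuinely open, and what validation on
synthetic data does and does not establish.

## 1. From events to signature matrices

Sensors log events, not samples: a bed sensor emits ON/OFF status
transitions, a toilet or fridge sensor emits single impulses, a power
meter reports a wattage that holds until the next report. All analysis
rests on a common substrate, the *signature matrix*: a regularly
resampled time x sensor matrix of home state, by default at 1-min
resolution — fine enough to retain short toilet or fridge activity,
coarse enough to keep a month of data small.

Conventions, chosen once and used everywhere:

* Bins are half-open `[t, t + w)`, left-aligned to the epoch minute, in
  UTC. A display timezone enters only at the reporting layer (daily
  aggregates, clock-time windows).
* A binary bin is active iff the sensor was ON during *any* instant of
  the bin (any-overlap). The alternative — majority occupancy — erases
  sub-minute events entirely; any-overlap keeps them at the cost of
  over-counting each session's boundary bins by at most one bin per end.
  The resampling-conservation tests bound exactly this: total active
  minutes differ from true ON time by at most two bins per session.
* Real-valued sensors get the time-weighted mean of the held value
  within the bin; binarization (needed by the profile and habit stages)
  is a strict threshold comparison, so raising the threshold can never
  activate a bin.
* An ON without a matching OFF at the end of a log is held open to the
  log end, with a warning — the conservative reading for occupancy
  sensors; overlapping ONs are coalesced.
* Malformed rows never abort ingestion. Field logs are dirty and
  keep-alives interleave with status traffic, so validation collects
  per-line errors into a report and continues.
* The nightly window defaults to 19:00–09:00, attributed to the day the
  window starts, so one night's sleep is one observation.

## 2. Behavior explanatory models (BEM)

For a per-day quantity (hours in bed, nightly hours, chair hours,
appliance hours, toilet or door counts) we fit the four-model pool over
feature subsets {bias}, {bias, trend}, {bias, weekend},
{bias, trend, weekend} and select by AIC = 2k − 2 ln L. Bias is always
present: it is the interpretable "average level" a caregiver reads first.
Real-valued quantities use ordinary least squares (penalized regressions
are excluded from the pool deliberately — a penalized likelihood is not
the L that AIC compares). Counts use Poisson regression; whenever a
member's Pearson dispersion exceeds 1.5, a negative-binomial refit of the
same feature set joins the pool and AIC arbitrates. The dispersion gate
avoids fitting the extra parameter when equidispersion is plausible, and
1.5 is far enough from 1 not to trigger on noise at 15–90-day windows.

Numerical conventions:

* The trend covariate is the day index scaled to [0, 1] over the window,
  so the fitted coefficient *is* the total change over the window (and
  the per-day slope is that divided by the window span). For count
  families the coefficient lives on the linear-predictor (log) scale.
* `k` is the degrees of freedom of the log-likelihood as R reports it,
  i.e. the gaussian family counts its variance parameter and the
  negative binomial its dispersion. Within one family the offset is
  constant across the pool, so selection is unaffected; the AIC identity
  2k − 2 ln L holds exactly for every member.
* Quartiles in the IQR pre-filter use linear interpolation (R type 7).
  With a constant series the IQR is 0 and the degenerate fence keeps
  every point equal to the quartiles — constants pass untouched.
* Pool members that fail to converge are marked failed and excluded from
  selection rather than poisoning it.

Outlier handling is two-stage, mirroring how such models are used in
practice: nulls and gross outliers are removed *before* fitting (IQR
fence, multiplier 1.5), then days whose standardized (gaussian) or
Pearson (count) residual exceeds 3 are flagged *after* fitting. The value
3 is our choice — the residual rule itself is standard; at 90-day windows
it flags about a day per season under pure noise.

One interaction is worth knowing: on clean series with a strong trend the
IQR screen occasionally trims legitimate extreme noise, which narrows the
residual-variance estimate and depresses trend-CI coverage by one to two
points. The package's CI-calibration experiments therefore run with the
screen disabled — they measure the regression's calibration, and their
generator plants no gross outliers for the screen to remove. On real
data, where gross outliers (sensor faults, visitors, hospital days) are
the reality the screen exists for, leave it on.

Rolling windows default to 15 days, stepping 1 day: long enough for a
4-parameter fit with screening, short enough to surface temporary trends.
Per-day coefficient vectors of the configured quantities are concatenated
into daily feature vectors (absent features and missing windows are
exported as 0 — AIC deselection means "no detectable effect", and a
constant dimension is what downstream classifiers need). User
discrimination trains a radial-kernel SVM on a stratified split and
reports macro-F1 with a confusion matrix; the 2-D view for visual
inspection uses classical multidimensional scaling of the standardized
feature space, the manifold projection available in base R — any
neighborhood-preserving projection serves, since it is read qualitatively
and never feeds back into the statistics. Single-user anomaly detection
wraps a one-class SVM with `nu` as the contamination bound (default
0.05, one flagged day per three weeks).

## 3. Sensor profiles and period comparison (SP)

A sensor profile is the expected activation level per time-of-day bin:
for state sensors the fraction of time active in the bin; for impulsive
sensors the probability of at least one activation. Bins default to
30 min (48/day) — the resolution at which morning routines, lunch, and
night visits remain distinguishable while 20-day periods still give
stable estimates.

The day is the statistical unit throughout: days are exchangeable
replicates of a routine, bins within a day are not. Confidence bands come
from a percentile bootstrap over days (default 1000 resamples, fixed
seed). Percentile, not normal-approximation: estimates near 0 and 1 are
the common case and the percentile interval respects [0, 1]. Bootstrap
quantiles use the type-6 empirical convention, whose interval coverage
sits closest to nominal for day-resampled 0/1 statistics at the 20–40-day
sample sizes the package targets; intervals are clipped to bracket the
point estimate. Coverage is verified by simulation in the test suite.

Two periods are compared bin by bin. The default test is a permutation
test of the difference in day-means (5000 label permutations, shared
across bins of one comparison, with the `(1 + #{|T*| >= |T|}) / (B + 1)`
p-value, so identical constant periods give exactly p = 1). A parametric
branch exists for larger samples: Welch's t for state sensors, a
two-proportion test for impulsive indicators. The 48 p-values of one
sensor's comparison form the multiplicity family, adjusted by the
Holm–Bonferroni step-down; this is the conservative reading (adjusting
across sensors as well would trade per-sensor power for a family nobody
reports on). Direction accompanies significance, since "increased
activity late morning" is the deliverable. Power grows with period
length, and the test suite checks this monotonicity at 10/20/40 days —
the flip side is that very long periods smooth over temporary changes,
which is why the comparison is meant to be run on rolling recent-vs-
reference windows, not ever-growing ones.

## 4. Multivariate habits clustering (MHC)

Per-sensor profiles are univariate. Recurring *days* — bed-heavy days,
chair-morning days — are multivariate objects, so the package learns a
compressed representation of whole daily matrices (binarized 30-min bins,
48 x sensors; 1-min input would multiply the sequence length by 30 for no
benefit at the scale of habits) and clusters in that space.

Two encoder architectures are provided, both trained under binary log
loss with mini-batch Adam (rmsprop and plain SGD are available):

* **GRU**: a single recurrent layer reads the day bin by bin; the final
  hidden state (default 32 units) is the embedding.
* **Conv1D**: two convolution blocks (16 and 8 filters, kernel 5,
  max-pool 2, ReLU), then a dense map to a 16-dim latent space.

Both decode through a single dense sigmoid layer from the latent vector
back to the full day. The encoder is what defines the embedding; a dense
decoder keeps the reconstruction objective identical while halving the
parameter surface that training has to move through, which on a CPU is
the difference between seconds and minutes per run. Weights are
Glorot-uniform initialized under the configuration seed; training is
deterministic given the seed; a non-finite loss aborts with a pointer at
the learning rate. Defaults (lr 0.01, 200 epochs, batch 16) were set to
satisfy the training-progress property — loss at least halved from the
first epoch — on 60–90-day planted-routine data, and nothing else.

The forward primitives (the GRU recurrence, the temporal convolution,
ReLU, the log loss) are exported and tested against independent
brute-force oracles to 1e-10; the convolution follows the sliding-window
(cross-correlation) convention of the deep-learning field.

Clustering defaults to mean-shift, which does not require a cluster
count. The implementation is the field-standard flat-kernel formulation:
points iterate to the mean of their bandwidth-neighborhood, and converged
modes within one bandwidth merge. The bandwidth is the k-nearest-neighbor
estimate — the mean distance to the `round(n * q)`-th neighbor — with
q = 0.2. The geometry behind the default: with a handful of habit modes
of comparable size, a neighborhood quantile approaching a mode's
population share spans the whole mode and bridges adjacent ones; 0.2
stays inside a mode while still absorbing day-to-day jitter. An explicit
`bandwidth` override exists, and duplicate-point degeneracy falls back to
a single cluster with a warning. k-means and spectral clustering are
available behind the same surface when a cluster count is known.

Reported per run: cluster labels; prototypes — the mean (or median) day
of each cluster *in the original sensor space*, which is what a caregiver
can read; the mean silhouette width; and the fraction of days in the five
largest clusters. The comparison baseline clusters raw concatenated
day vectors with the same algorithm and distance. Silhouettes are
computed in the space each method actually clusters in — embedding for
the autoencoder variants, raw space for the baseline. This matches how
each method "sees" the data; comparing both in a single space would
silently privilege whichever method that space belongs to, so the
convention is stated prominently here instead.

## 5. Stream rules

The pilot-management rules are replayed in batch over a log, which at
desk scale is behaviorally identical to live evaluation: low battery
(latest report strictly below threshold, default 20%), keep-alive gap
(silence longer than a multiplier — default 2 — times the sensor's
heartbeat interval), prolonged state (continuously ON longer than a
maximum, e.g. 480 min for a front door). Strict inequalities at
thresholds; one ongoing condition yields one alert, timestamped at the
threshold crossing. The defaults are ours — operational policy, not
statistics — and are plain parameters.

## 6. The synthetic household

The simulator exists so that every stage has ground truth. It emulates a
single-occupant home as:

* **Impulsive sensors** (toilet, fridge, door, PIR): inhomogeneous
  Poisson processes with a 48-bin rate profile (events/h), drawn by
  thinning against the day's maximum rate.
* **Session sensors** (bed, chair, TV meter): a daily session count
  (Poisson with a floor — the bed keeps a floor of 1, since a day with no
  sleep session would be unrealistic), start times from a 48-bin density,
  durations truncated-normal with a 1-min floor, overlapping sessions
  merged. TV sessions emit power readings at on/off and periodically in
  between.
* **Modulation**: weekend multipliers on Saturdays/Sundays; linear trends
  ramping the daily expectation from its base value to base + total
  change across the window (so a linear-trend BEM is correctly
  specified — parameter recovery is then a clean test); changepoints
  switching a sensor to a new routine from a given day; outlier days
  scaling rates or durations.
* **Plumbing**: keep-alives every heartbeat interval, a linearly decaying
  noisy battery trace (about 8 months to empty; illustrative only — it
  exists to exercise the battery rule, not to model chemistry).

Everything is deterministic given the scenario seed, byte for byte. The
default full-home scenario was calibrated once, by simulation, to the
regime the analytics are designed for — on the order of 110 status events
per day with PIR contributing roughly half — and then frozen.

Two auxiliary generators serve specific studies. `simulate_profile_days`
draws day-level bin statistics directly: Beta-distributed active
fractions around a target profile with concentration 10 (day-to-day
habit jitter of a steady routine; at p = 0.4 that is a spread of about
±0.14), or Bernoulli activation indicators. `simulate_pattern_days`
plants habit modes as per-sensor session blocks with ~1-bin start and
duration jitter, plus a configurable share of structureless noise days —
the ground truth for clustering studies, with the adjusted Rand index
evaluated on the non-noise days (noise days have no true label to
recover; where they land is reported by the coverage metric instead).

What the simulator does *not* model — and what passing tests therefore do
not establish about real homes: multiple occupants and visitors, sensor
faults and dropouts beyond whole-day outliers, seasonal and holiday
structure, cross-sensor causal coupling (the simulated bed and chair do
not know about each other), and annotation of any kind. Results on real
pilot data depend on those; the synthetic validation establishes that the
machinery is correct and calibrated under its own assumptions, not that
the assumptions hold in any particular home.

## 7. Problem sizes used in validation

The test suite and the acceptance script size their simulations to what
the methods are meant for: 60–90-day windows for BEM recovery (500
replicates), 20+20-day periods with 48 bins for comparison error control
(500 null replicates, 2000 permutations per test) and power (200
replicates, with the length study at 10/20/40 days), 40 days for
bootstrap coverage (500 replicates, 1000 resamples), and 72-day
three-mode data with 10% noise days for clustering (20 seeds, 120
epochs). These are the package's study conditions; changing them changes
the questions, not the code.

## 8. Known limitations

* The GRU embedding dimension, layer counts, epochs and the clustering
  bandwidth quantile are defaults with stated rationale, not tuned
  optima; real deployments should expect to revisit them.
* AIC-based selection is greedy about parsimony at short windows: a real
  but small weekend effect inside a 15-day rolling window will often be
  deselected. That is by design (interpretability first) but worth
  remembering when reading feature vectors.
* Post-selection confidence intervals (reading the CI of a coefficient
  from the AIC-selected model) are mildly optimistic; at the effect sizes
  the package targets the selection event is near-certain and the effect
  negligible, but it is not zero in general.
* The permutation comparison shares one set of label permutations across
  bins. That is valid (each bin's marginal null is exact) and fast, but
  p-values across bins are positively dependent — harmless under Holm,
  which is valid under arbitrary dependence.
* Battery traces and keep-alive scheduling are idealized; the stream
  rules are tested against them, not against real radio behavior.
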