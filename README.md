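# esnclass

Backpropagation-free time series classification with echo state networks,
for two data shapes that usually need two different tools:

* **regular series** — equal length, evenly sampled, labelled (the classic
  benchmark setting): sensor traces, ECG beats, motion captures;
* **irregular longitudinal series** — a handful of visits per participant
  at uneven intervals, as produced by cancer-screening programmes where
  biomarkers such as CA125 are measured whenever a participant happens to
  attend, and where *forecasting an outcome months before the last visit*
  is the clinically interesting task.

The package is aimed at biostatisticians and ML practitioners who want
recurrent-network expressiveness without backpropagation: all recurrent
weights are random and fixed, and only a linear readout is ever trained,
so a full 50-seed robustness study runs in seconds on a laptop.

## The methods

Both classifiers share one dynamical core, the leaky-integrator echo state
network with the output-feedback loop removed:

```
x_{t+1} = (1 - a) x_t + a tanh(W_in u_{t+1} + W_res x_t),   x_0 = 0
```

`W_in` (M×k) and `W_res` (M×M) are standard-normal draws, `W_res` rescaled
to spectral radius ρ (< 1, so initial conditions fade — the echo state
property). The state is reset to zero for every sample.

**Diff-ESN** (`diff_esn()`, regular series). Each series is encoded as its
adjacent pairwise differences `û_j = u_{j+1} − u_j` — static suppression:
constant levels cancel exactly, abrupt change survives. The differenced
sequence drives the reservoir and each sample is summarised by the
*variance hallmark*, the per-neuron variance over time of the states. A
linear SVM on the stacked hallmarks (one-vs-rest beyond two classes) does
the classification.

**Interp-ESN** (`interp_esn()`, irregular cohorts). Markers are
standardized with training-cohort statistics, linearly interpolated and
resampled monthly since each participant's first record, and driven
through the reservoir. The states are stacked with *skip sampling*: every
τ-th row counting backwards from the last month (the last state is always
kept), each row labelled with its participant's outcome. A linear SVM
with a seeded Platt-calibrated probability output scores the rows, and
the participant's prediction is the probability at the last retained row.
Forecasting γ months ahead truncates only the test participant's monthly
rows to the first `m − γ` and leaves training untouched.

Evaluation mirrors how such methods should be reported: error-rate
distributions over 50 reservoir seeds (`seed_robustness()`), noise
robustness with σ = scale × max |train| perturbations, ROC-AUC over 50
random 50-50 cohort splits (`split_robustness()`), and a last-timepoint
logistic regression reference (`last_point_baseline()`). Synthetic
generators (`gen_regular()`, `gen_cohort()`) reproduce both data shapes
deterministically so every claim is testable offline.

## Worked example

```r
library(esnclass)

## regular series: two classes differing in burst timing and magnitude
d <- gen_regular(n_per_class = 100, length = 100, seed = 1)
fit <- diff_esn(d$train$x, d$train$y, M = 50, a = 0.9, seed = 1)
fit
#> Differential echo state network classifier
#>   reservoir: M = 50 , a = 0.9 , rho = 0.95 , seed = 1
#>   readout: linear SVM (cost 1), 2 classes: 1, 2
#>   trained on 200 samples
error_rate(d$test$y, predict(fit, d$test$x))
#> [1] 0.03

## irregular screening cohort: 222 participants, 6 markers, <= 6 visits
ch <- gen_cohort(n = 222, seed = 1)
ch
#> Irregular longitudinal cohort: 222 participants, 6 markers
#>   visits per participant: 2 - 6
#>   outcomes: control = 148, case = 74
split_robustness(ch, n_splits = 10, tau = 4, M = 50, baseline = TRUE,
                 seed = 1)
#> Evaluation report: roc_auc over 10 runs
#>   esn          mean 0.972  (95% CI 0.962 - 0.981)
#>   baseline     mean 0.994  (95% CI 0.990 - 0.998)
```

3% test error from the burst timing/magnitude contrast, and a 0.97 mean
AUC on the screening cohort. On this late-rise cohort the last-point
baseline is also strong (cases are several SD elevated at their final
visit); the trajectory model's advantage appears where the signal is in
the *shape* — see the slope-only experiment in the vignette, where the
baseline collapses to chance (AUC ≈ 0.5) while Interp-ESN stays near 0.8
and wins every split.

A thin command-line front end over the same functions lives in
`inst/cli/esnclass.R` (subcommands `diff-esn`, `interp-esn`,
`synth-regular`, `synth-cohort`; every run appends a JSON-lines record of
config and metrics).

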