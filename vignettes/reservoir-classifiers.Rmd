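---
title: "Reservoir classifiers for regular and irregular time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reservoir classifiers for regular and irregular time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(esnclass)
```

## The model

Both classifiers in this package are built on the same fixed random
dynamical system, a leaky-integrator echo state network. An input sequence
$u_1, \dots, u_n \in \mathbb{R}^k$ drives an internal state
$x_t \in \mathbb{R}^M$ by

$$x_{t+1} = (1 - a)\,x_t + a \tanh(W_{in} u_{t+1} + W_{res} x_t),$$

with $x_0 = 0$ and the state reset to zero for every sample, so no
dependency leaks between samples. $W_{in}$ ($M \times k$) and $W_{res}$
($M \times M$) are drawn once from the standard normal distribution and
never trained; $W_{res}$ is rescaled so that its spectral radius equals a
target $\rho$. There is no output-feedback term and no trained per-step
output layer: classification happens entirely downstream of the states,
which is what makes the whole approach backpropagation-free. Because the
update is a convex combination of the previous state and a $\tanh$ value,
every state coordinate stays strictly inside $(-1, 1)$.

With $\rho < 1$ the network has the echo state (fading memory) property:
two trajectories driven by the same input from different initial states
converge, so the state is asymptotically a function of the recent input
history only. `esp_profile()` measures this convergence directly and the
test suite checks it for 50 independent reservoir draws.

### Key parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `M` | reservoir neurons | 50 | small enough to be near-instant, large enough for a rich state; the study configuration throughout |
| `a` | leakage rate (dimensionless, $[0,1]$) | 0.9 | conventional "slightly below 1"; sets the state's memory time scale |
| `rho` | spectral radius of $W_{res}$ | 0.95 | preserves the echo state property with long usable memory |
| `input_scale` | multiplier on $W_{in}$ | 1 | raw standard-normal draws; see the saturation discussion below |
| `tau` | skip-sampling step (months) | 4 | tumour doubling times of a few months make 3–6 sensible |
| `cost` | SVM regularisation weight | 1 | no tuning is performed anywhere; reported results are un-tuned |

## Method 1: differential encoding + variance hallmark

For equal-length regular series (`diff_esn()`), each sample is first
transformed into adjacent pairwise differences
$\hat u_j = u_{j+1} - u_j$. The encoding is loosely neuromorphic: most
transformed observations lie near zero (sparsity) and only abrupt change
survives (static suppression). It also makes the entire pipeline exactly
invariant to constant offsets of a sample.

The differenced sequence drives the reservoir and the per-sample feature
vector is the *variance hallmark*: the variance over time of each neuron's
state sequence, a fixed $M$-vector per sample. A linear SVM is trained on
the stacked hallmark rows. For more than two classes the package fits an
explicit one-vs-rest battery of binary machines and predicts by the
largest oriented decision value (first-level wins on exact ties, which
occur with probability zero for continuous features).

Two numerical choices deserve a note:

* **Variance denominator.** The hallmark uses the population variance
  (divide by $n$). It is a fixed per-sample summary, not an estimator of a
  population moment; with equal lengths the choice is a global column
  scaling absorbed by the SVM.
* **Feature scaling.** Raw variances are fed to the SVM by default
  (`scale_features = FALSE`); the stacked design matrix is used exactly as
  defined. Optional z-scaling is available but not part of the reference
  pipeline. Constant samples produce all-zero feature rows and are passed
  through unchanged.

## Method 2: interpolation + skip sampling

Screening-style longitudinal data (`interp_esn()`) are irregular in the
worst ways: a handful of visits per participant (often 2–6), uneven
intervals, and participant-controlled timing. The pipeline is:

1. **Standardize** each marker by its training-cohort mean and SD (pooled
   over visits). The statistics are frozen into the fitted object and
   reapplied at prediction time, so the test split never leaks into them.
2. **Interpolate** each participant's markers piecewise-linearly and
   resample at months $0, 1, \dots, \lfloor \text{span} \rfloor$ since
   their first record. Linear, not cubic: with fewer than six knots a
   nonlinear trajectory model is not identifiable. The exact last-visit
   value is appended as a final row when the last visit falls between
   integer months, because the most recent screen is the clinically
   decisive one and must never be lost to the grid.
3. **Run the reservoir** over the monthly sequence, reset per participant.
4. **Skip-sample** the states: keep every $\tau$-th row counting
   *backwards* from the last month (`skip_select()`), so the last state is
   always retained; `tau = 1` keeps everything. This controls the design
   matrix size while the recurrent state keeps carrying the in-between
   history. `tau` may not exceed the shortest monthly sequence in the
   training cohort.
5. **Classify rows** with a linear SVM whose decision values are mapped to
   probabilities by Platt-style sigmoid calibration, fitted on
   out-of-fold decision values from a seeded 5-fold split. The calibration
   is written in-package because the usual libsvm probability machinery
   draws from a process-global C RNG and therefore cannot reproduce a
   report bit-for-bit; the seeded construction makes
   `identical seed list → identical report` hold exactly.
6. **Aggregate per participant**: the participant's prediction is the
   probability at the last retained row — the state that has absorbed the
   whole history.

Forecasting $\gamma$ months ahead reuses the trained model unchanged and
simply truncates each *test* participant's monthly sequence to its first
$m_i - \gamma$ rows before steps 3–6. Participants whose truncated series
would be empty are excluded and reported. The forecast prediction is the
probability at the new last row.

## Synthetic data: what it emulates, what it does not

Both generators are seed-deterministic (bit-exact regeneration) and leave
the caller's RNG stream untouched.

**`gen_regular()`** emulates equal-length benchmark series whose classes
differ in the timing and magnitude of abrupt local change: Gaussian
baseline noise (SD 0.1) with a class-specific amplitude multiplier inside
a class-specific burst window. The default archetypes use disjoint
30%-long windows with amplitude multipliers 5 and 11. Those defaults were
derived from the signal-detection arithmetic of the hallmark, not fitted
to anything: the per-sample variance of a 30-step burst has a relative
sampling SD of about $\sqrt{2/30} \approx 26\%$, so a roughly four-fold
between-class burst-variance ratio puts the class contrast well clear of
the sampling noise. A quiet baseline matters for a second reason: the
differenced inputs must not saturate the $\tanh$, or amplitude structure
is squashed (see below).

**`gen_cohort()`** emulates a screening case-control cohort: 222
participants by default, 2–6 visits at 4–14-month gaps, six standardized
markers, binary outcome, a participant-and-marker baseline
(SD 0.7) plus visit noise (SD 0.7). Cases rise linearly on three affected
markers from 18 months before their *last* visit at 0.15 SD/month —
anchoring onset to the last visit mirrors risk rising towards diagnosis
and guarantees that a 6-month-earlier forecast still has signal to find.
`slope_only = TRUE` re-parameterises the rise so cases arrive *at* their
baseline by the last visit: last-visit marginals are then equal between
groups by construction and the only class signal is the trajectory slope.

Neither generator attempts pharmacokinetics, tumour-growth kinetics,
informative visit timing, missing markers, or survival censoring. Passing
the recovery tests therefore shows that each pipeline extracts the kind of
structure it was designed for — localized change-level contrasts, or
level/slope trajectories on a handful of markers — not that it matches any
particular clinical dataset.

## Saturation and slope-coded signals

One genuinely open design point deserves emphasis. With $k$ standardized
markers and standard-normal input weights, pre-activations have SD around
$\sqrt{k}$, so for $k = 6$ the $\tanh$ operates mostly saturated. For
*level-coded* signals (cases shifted by several SD, as in the late-rise
cohort) saturation is harmless — sign patterns flip and the state
separates classes easily. For *slope-coded* signals the class information
lives in modest recent-history differences, and saturation destroys it:
on the slope-only cohort the last-row states are unreadable at
`input_scale = 1` but cleanly separable at `input_scale = 0.1` (the probe
is reproduced in the package sources). The slope-only baseline-dominance
experiment is therefore run at `input_scale = 0.1`, the quasi-linear
regime the signal demands; the reservoir default stays at 1 because the
reference pipelines specify raw standard-normal input weights. Users with
subtle, slope-like signals should treat `input_scale` as the first knob to
turn.

## Evaluation protocols

* `error_rate()` is the plain misclassification fraction.
* `roc_auc()` is the probability that a random positive outscores a
  random negative, ties counted half; the score direction is pinned
  (higher = more positive), so a worse-than-chance model reports below
  0.5 instead of being silently flipped.
* `seed_robustness()` re-runs the whole Diff-ESN pipeline per reservoir
  seed — new random connections each time — optionally perturbing the
  test set with Gaussian noise of SD `scale` × max |train| (fresh noise
  per run); it reports all per-run values, their mean, and a
  normal-approximation 95% CI of the mean (SD/$\sqrt{n}$), the standard
  symmetric summary for ~50 replicates.
* `split_robustness()` draws unstratified random 50-50 train/test halves
  of a cohort; standardization is recomputed on each training half; the
  reservoir is held fixed across splits so the protocol isolates split
  variability. Splits that land a single class in either half cannot be
  scored; they are redrawn and the redraw count is reported.
* `last_point_baseline()` is the reference the trajectory model must
  justify itself against: logistic regression on last-visit marker values
  only.

No multiple-testing correction is applied anywhere: the reports are
descriptive distributions, not hypothesis tests.

### Problem sizes in the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) use
the study configuration throughout: 100 train / 100 test samples of length
100 for the regular task with 50 reservoir seeds; the 222-participant
cohort with 50 random splits, `tau = 4`, `M = 50`, and a 6-month forecast
horizon. On one CPU the full acceptance run takes about three minutes.

## Known limitations

* The variance hallmark is order-free given the state trajectory; timing
  information enters only through the reservoir's fading memory. Signals
  distinguished purely by *when* an otherwise identical burst occurs are
  separated only weakly, via decay-tail truncation at the sequence end.
* Linear interpolation between sparse visits invents no variation, so the
  differential method is deliberately not offered on cohort data: the
  variance of an interpolated trajectory mostly reflects the visit grid.
* The probability readout calibrates row-level scores; rows of one
  participant are correlated, so calibrated probabilities are honest
  rankings but not strict frequency statements.
* Error rates and AUCs are reported as distributions over seeds/splits;
  the package deliberately provides no single-seed headline numbers.
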