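---
title: "Finding climate windows: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding climate windows: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climwindow)
```

## The problem

Biological responses — laying dates, body condition, survival — often react
to a climate variable over some *window* of time before the response is
measured (mean temperature in early spring, say). Choosing that window by
hand risks missing the period of real sensitivity and biases any downstream
conclusion. `climwindow` searches over windows systematically: every
candidate window is scored by how much adding its aggregated climate to a
user-chosen baseline regression improves the sample-size-corrected AIC.

Two searches are provided. The **sliding-window** search (`slidingwin()`)
is exhaustive: for a range of `range_max` down to `range_min` days (or
weeks/months) before the reference date it fits all
`m (m + 1) / 2` contiguous windows, where `m` is the number of offsets —
67,161 models for a full year of daily data. The **weighted-window** search
(`weightwin()`) replaces the implicit uniform weighting of a window by a
continuous Weibull or GEV weight curve over the whole climate history and
optimizes its three parameters (shape, scale, location) directly.

## The model

The user supplies a baseline model `response ~ covariates` (gaussian,
poisson, or binomial) that deliberately contains no climate term. For a
candidate window $[e, s]$ (offsets in days before the, possibly
reference-adjusted, measurement date) the climate is aggregated row-wise —
mean, maximum, minimum, sum, or within-window slope — and appended to the
baseline under a chosen functional form (linear, quadratic, cubic, log,
inverse). Support for each window is

$$\Delta\mathrm{AICc} = \mathrm{AICc}(\text{climate model}) -
  \mathrm{AICc}(\text{baseline}),$$

with $\mathrm{AICc} = -2\log L + 2\rho + 2\rho(\rho+1)/(N-\rho-1)$.
Negative values favour the climate model, and the model set is ranked
ascending so the best window comes first. $\rho$ counts every estimated
parameter, including the gaussian residual variance (an intercept-only
gaussian baseline has $\rho = 2$); this constant-offset convention cancels
in $\Delta$AICc. Natural logarithms throughout.

Two anchorings are available. *Relative* windows count back from each
record's own measurement date. *Absolute* windows first move every record
to a fixed reference day and month (`refday`), keeping its year — suitable
when all records in a year share one climatic history. The replacement is
applied verbatim even when the reference date falls after a measurement
date; a warning flags those records because the design question is
biological, not computational. Within-group centring (`centre`) splits a
window's aggregate into group means and within-group deviations so
between- and within-group climate sensitivity get separate coefficients.

## Multi-model inference

Climate series are autocorrelated, so neighbouring windows fit almost
equally well. Akaike weights
$w_i \propto \exp(-\tfrac12 \Delta\mathrm{AICc}_i)$ quantify this: the
**confidence set** is the longest prefix of the ranked set whose
cumulative weight stays at or below the level (0.95 by default; the
crossing record is excluded, and the set is never empty). Its size as a
share of all windows, the **C statistic**, is small when support
concentrates on few windows and large on signal-free data.
`model_average()` sums slopes weighted by the *full-set* weights
(deliberately not renormalized within the subset), and `medwin()` reports
the weight-weighted median start and end of the confidence set (the first
offset at which the cumulative within-set weight reaches one half; a plain
median is available via `weighted = FALSE`).

## Error control

Searching thousands of windows invites false positives.
`randwin()` builds the null by permuting the biological date column —
responses keep their covariates, the climate series keeps its
autocorrelation — and rerunning the whole analysis. Two metrics follow:

* `p_delta_aicc()`: the continuity-corrected rank
  $(r+1)/(\text{repeats}+1)$ of the observed best ΔAICc within the
  randomized best ΔAICc values, never exactly zero and reported as
  `< 1/(repeats+1)` when the observed value beats every rerun. Needs many
  repeats (hundreds) to be informative.
* `p_c()`: a logistic calibration mapping $\Delta C$ (observed C minus the
  median randomized C, proportions) and sample size $N$ to the probability
  that the result is spurious, usable with as few as 5 repeats. Without
  cross-validation the linear predictor is
  $-0.54 + 1.95\,\Delta C + 0.08\,N + 0.31\,\Delta C\,N$; with 10-fold
  cross-validation, $-0.62 + 11.56\,\Delta C + 0.06\,N + 6.88\,\Delta C\,N$.
  The coefficients are taken as given; refitting the calibration is out of
  scope.

**Orientation of `p_c`.** The calibration is published as
$P_C = 1/(1+\exp(\eta))$ with $\eta$ the linear predictor above. Evaluated
verbatim this *rises* towards 1 for strong signals (large negative
$\Delta C$ makes $\eta$ very negative), which contradicts the reading
"small $P_C$ means the signal is unlikely to be chance". Because the
calibration was fitted as a logistic model of *signal-is-real*, the
complement $1/(1+\exp(-\eta))$ carries that meaning, and it behaves
correctly on synthetic data: near 0 under strong signals, near 1 on null
data at moderate $N$. We expose both: `orientation = "verbatim"` (the
default, the formula exactly as published) and `orientation = "flipped"`
(the complement). Everything that *classifies* — `performance_study()` and
its false-positive/negative rates under the $P_C < 0.5$ rule — uses the
flipped orientation, since the verbatim one cannot classify. The two sum
to one, so no information is lost either way.

## Cross-validated ΔAICc

With `k > 0`, `slidingwin()` replaces each window's ranking score by a
k-fold cross-validated ΔAICc (gaussian responses only; an explicit error
otherwise, because the score is MSE-based). Records are split into `k`
near-equal random folds (seeded; the seed is a required, logged part of
the configuration). Per fold, window model and baseline are fitted on the
training rows and scored on the held-out rows via

$$\mathrm{AICc}_{\text{fold}} = n_{\text{test}} \log(\mathrm{MSE}_{\text{test}})
  + 2\rho + \frac{2\rho(\rho+1)}{N-\rho-1},$$

and the fold differences are averaged. Two numerical choices matter here.
The likelihood term is scored over the $n_{\text{test}}$ rows actually
predicted: scoring it with the total $N$ makes the per-fold log-MSE
average downward-biased for small folds (Jensen), to the point that
cross-validated ΔAICc becomes *more* negative than the non-CV value —
the opposite of its purpose. With $n_{\text{test}}$ the scores shrink by
roughly a factor $k$ and behave conservatively, which is also why CV
ΔAICc values look an order of magnitude smaller than their full-data
counterparts. The small-sample penalty keeps the total $N$, because a
fold-size penalty is undefined whenever a fold has fewer than $\rho + 2$
rows (routine at $k = 10$ with small $N$). `aicc_cv_value()` exposes both
via its `n_lik` argument. Selection uses the CV score, but reported
coefficients and $R^2$ always come from full-data refits.

The point of CV here is bias control: the best window's $R^2$ is
optimistic because it won a search over thousands of candidates, and CV
selection reduces that optimism (the acceptance suite measures this at
$N = 47$, true $R^2 = 0.2$, 200 datasets).

## The weight curves

`weight_curve()` evaluates the chosen density on normalized time: offset
$j$ maps to $t_j = (j - \text{range}_{\min} + 0.5)/m$, the midpoint of the
day's interval on $[0, 1]$. Normalizing time makes scale and location
parameters comparable across ranges (a scale of 0.2 means a fifth of the
searched history regardless of whether that is 60 or 365 days). The
density is shifted by the location, evaluated at the midpoints, and
normalized by its *sum*, so the weights are exactly a discrete probability
distribution; an all-zero density (e.g. a location beyond the range) is a
hard error, and the optimizer treats it as a penalty. The Weibull family
(shape, scale > 0; zero left of the location) covers monotone decay —
shape 1 is the exponential, fading-memory case — through unimodal bells.
The GEV family adds left- and right-skewed shapes; its Gumbel limit is
taken when |shape| < 1e-6 to avoid the numerical instability of the
general form near zero. No installed package provides the GEV density, so
it is written out here (three lines, including the Gumbel branch).

`weightwin()` minimizes ΔAICc over (shape, scale, location) with bounded
L-BFGS-B (finite-difference gradients; bounds default to shape
[0.01, 20] (Weibull) or [−5, 5] (GEV), scale [0.01, 5], location [−5, 5]
on normalized time, all user-overridable). The objective is not smooth
everywhere: after normalization, (shape, scale, location) trade off along
curved ridges on which many parameter triples produce nearly identical
weight vectors. Two safeguards address this, both switchable:

* a 27-point fixed lattice pre-scan (`prescan = TRUE`) launches the search
  from the best of the lattice and the user's `par0` — the user start is
  kept unless a lattice point is strictly better;
* up to `restarts` rounds alternating a Nelder–Mead pass with the bounded
  quasi-Newton pass, stopping when a restart no longer improves. Simplex
  proposals outside the bounds are penalized, keeping the search in the
  box.

Without these, a noticeable fraction of plausible starts stalls far from
the optimum. A practical consequence of the ridge structure: the *weight
vector* is well identified, the raw parameter triple is not. Interpret the
fitted curve, not the fitted shape parameter.

`explore()` tabulates a curve for given parameters so starting values can
be chosen by eye before optimizing, and `weightwin` reports its full
objective trace, convergence flag, and evaluation count.

## Synthetic data and what passing tests mean

`gen_dataset()` emulates an annual study: a daily AR(1) gaussian climate
(unit marginal variance; lag-1 autocorrelation 0.2 by default) spanning
the study years plus a lead-in, one record per year on a fixed measurement
date (1 June by default), and a response that is linear in the mean
climate of a known true window (40–20 days before measurement by default,
slope 1) plus gaussian noise. The noise variance solves
$R^2 = \mathrm{Var(signal)}/(\mathrm{Var(signal)} + \sigma^2_\varepsilon)$
using the empirical variance of the windowed means, so the target $R^2$ is
a property of each generated series; `target_r2 = 0` removes the climate
term entirely, and `target_r2 = 1` is the noiseless boundary used by
construction tests. The default autocorrelation of 0.2 represents
short-lag persistence of a de-seasonalized anomaly series; it makes
neighbouring windows correlated without letting a single weather spell
dominate the history.

What the generator does *not* emulate: seasonality, trends, heavy tails,
spatial replication, within-year variation in measurement dates, or
observation error in the climate itself. Passing tests therefore show the
machinery is correct and well calibrated under clean conditions, not that
a given field dataset meets those conditions.

`performance_study()` wires the pieces together over a grid of sample
sizes and signal strengths: per dataset a sliding search, a 5-repeat
randomization, and classification by flipped $P_C < 0.5$, tabulating
false-negative/false-positive rates and the median estimated $R^2$.

## Problem sizes and numerical choices

The test and acceptance suites run on deliberately scaled-down problems:
search ranges of 10–60 days, 100–200 replicate datasets, and 49–99
randomization repeats, sizes at which every check runs in seconds to a few
minutes while the statistical behaviour under test is already expressed.
For gaussian linear fits the per-window regressions are computed exactly
by residualizing the response and all window aggregates against the
baseline design (QR once, then rank-one updates) — algebraically identical
to refitting each window with `lm`, and verified against such an oracle in
the tests; other families and functional forms refit per window. Other
conventions: ties on ΔAICc go to the shorter window, then the later end;
windows whose model cannot be fitted (log of a non-positive aggregate, a
climate term collinear with the baseline, the degenerate single-day slope)
are kept as flagged rows so the set size is always $m(m+1)/2$, and their
weights are `NA` with the remainder renormalized; missing climate days
inside the required span are a hard error — no silent imputation; the
confidence-set prefix rule uses a 1e-9 tolerance on the cumulative weight
so exact-uniform weights are not truncated by floating-point rounding.

## Known limitations

Single climate variable and a single contiguous (or single-peaked) signal
per analysis; mixed-effects and survival baselines are not wired in (the
fit adapter is the extension point); `weightwin` tests mean climate only;
the $P_C$ calibration is used as published and its printed orientation
issue is documented above rather than resolved; sub-daily climate data and
gridded inputs are out of scope.
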