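# climwindow

Tools for finding the **climate window** — the period of time before a
biological measurement over which a climate variable best explains the
response. Typical users are ecologists and epidemiologists relating annual
traits (laying dates, body mass, counts, survival) to daily weather
records, who would otherwise pick "spring temperature" or similar by hand.

## What it computes

For a baseline regression `response ~ covariates` (gaussian, poisson, or
binomial) with no climate term, every candidate window `[end, start]` in
days (or weeks/months) before the — possibly reference-adjusted —
measurement date is scored by appending its aggregated climate (mean, max,
min, sum, or slope; linear through cubic, log, or inverse form) and
computing

    ΔAICc = AICc(climate model) − AICc(baseline),
    AICc  = −2 log L + 2ρ + 2ρ(ρ+1)/(N − ρ − 1)

so negative values favour the climate model. The package provides:

* `slidingwin()` — exhaustive search over all `m(m+1)/2` windows in a
  range (67,161 models for a full year of daily data), ranked ascending by
  ΔAICc, with optional k-fold cross-validated scoring;
* `weightwin()` — a parametric alternative: a Weibull or GEV weight curve
  over the whole climate history, with shape/scale/location fitted by
  bounded quasi-Newton minimization of ΔAICc;
* multi-model inference — `akaike_weights()`, `confidence_set()`, the
  `c_statistic()` (share of windows in the confidence set),
  `model_average()`, `medwin()`;
* randomization error control — `randwin()` (date-permuted null reruns),
  `p_delta_aicc()` (rank-based), `p_c()` (logistic calibration usable with
  as few as 5 reruns);
* a synthetic-data generator (`gen_dataset()`, `gen_climate()`) and a
  misclassification/bias harness (`performance_study()`);
* heat-map plots (`plot_delta()`, `plot_weights()`), CSV/YAML
  serialization, and a thin command-line wrapper
  (`inst/cli/climwindow.R`, subcommands `slide`, `weight`, `rand`,
  `pvalue`, `synth`, `plot`).

## Worked example

Forty-seven annual records whose response depends on mean climate 40–20
days before a 1 June measurement (slope 1, signal R² = 0.4, AR(1) daily
climate):

```r
library(climwindow)
dat <- gen_dataset(n_records = 47, true_window = c(40, 20), beta = 1,
                   target_r2 = 0.4, seed = 42)
ms <- slidingwin(response ~ 1, dat$climate, dat$biol, range = c(60, 0))
print(ms, 3)
#> <window_modelset> 1891 windows (mean/lin, relative, range 60-0 day)
#>   window_start window_end delta_aicc     beta        se flag mod_weight
#> 1           38         17  -27.73137 1.110555 0.1750982      0.06849459
#> 2           38         18  -27.60735 1.118222 0.1768012      0.06437641
#> 3           40         17  -26.98756 1.153420 0.1849590      0.04722147
```

The best window (38–17 days before measurement, ΔAICc −27.7) closely
overlaps the generating window, and its slope estimate 1.11 ± 0.18 covers
the true value 1. Neighbouring windows fit almost equally well — that is
what the inference layer is for:

```r
c_statistic(ms)                        # 9.3: the 95% set is 9% of windows
medwin(ms)                             # start 39, end 17
model_average(confidence_set(ms))      # 1.071
rnd <- randwin(99, "sliding", response ~ 1, dat$climate, dat$biol,
               seed = 1, range = c(60, 0))
p_delta_aicc(ms$dataset$delta_aicc[1], rnd)
#> <pvalue_report> P_dAICc = < 0.01
p_c(c_statistic(ms), rnd, n = 47, orientation = "flipped")
#> <pvalue_report> P_C = 3.21e-05 (delta_C = -0.821)
```

No date-permuted rerun reached the observed ΔAICc (P below the resolution
of 99 repeats), and the calibrated P_C is vanishingly small: the signal is
real. The parametric search agrees while describing the memory as a
smooth curve:

```r
weightwin(response ~ 1, dat$climate, dat$biol, range = c(60, 0),
          par0 = c(3, 0.2, 0))
#> <weighted_result> weibull weight curve
#>   delta_aicc = -27.838, shape = 1.617, scale = 0.235, location = 0.270
#>   beta = 1.298 (se 0.204), converged: TRUE, 1324 evaluations
```

`plot_delta(ms)` and `plot_weights(ms)` draw the ΔAICc landscape and the
95/50/25% confidence-set membership over (window start, window end).

See the vignette (`vignettes/climate-window-analysis.Rmd`) for the model,
the cross-validation and P_C conventions, optimizer design, and what the
synthetic generator does and does not emulate.

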