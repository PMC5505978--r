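# rrgamma

Heart-rhythm state characterization from RR-interval tachograms, built
around two ideas:

1. **Induced time series.** A tachogram (the sequence of inter-beat RR
   intervals) carries more information than its summary statistics
   reveal. Applying the forward finite difference
   `dx/dt[n] ≈ (x[n+1] − x[n]) / (t[n+1] − t[n])` repeatedly produces
   derivative series up to order 10 — heart-rate velocity, acceleration,
   jerk, and beyond — whose means and standard deviations form a
   22-variable state space for rhythm discrimination.
2. **The γ metric.** Each rhythm group (normal sinus rhythm, NSR;
   atrial fibrillation, AF) is modelled in a selected-variable space as
   the 1-SD ellipsoid of its mean μ and covariance Σ. With
   `u = (μ₂ − μ₁)/‖μ₂ − μ₁‖` and `r_k = 1/√(uᵀ Σ_k⁻¹ u)` the radius at
   which the mean–mean axis pierces group k's ellipsoid surface,

       d = (‖μ₂ − μ₁‖ − r₁ − r₂) / (r₁ + r₂),   γ_M = Σ_{k1>k2} d_{k1k2}

   is a normalized surface-to-surface separation: positive when the
   ellipsoids clear each other along that axis, −1 when centers
   coincide. In one dimension it reduces to
   `(|μ₁ − μ₂| − (σ₁ + σ₂)) / (σ₁ + σ₂)`. Exhaustively ranking variable
   subsets by γ picks a handful of induced variables that let a plain
   unregularized logistic regression separate NSR from AF even on
   observation windows of a few seconds.

The package is aimed at researchers in heart-rate-variability analysis
and developers of embedded arrhythmia screeners: it provides the full
pipeline — tachogram construction, derivative stacks, feature
extraction, univariate and multivariate γ analysis, classification and
observation-time sweeps — plus the beat-level perturbation models
(timing jitter, missing beats, premature atrial/ventricular
contractions) used to study robustness, and calibrated synthetic NSR/AF
generators so everything runs without clinical recordings.

## Worked example

```r
library(rrgamma)

ds <- make_dataset(n_nsr = 200, n_af = 130, duration_s = 60, seed = 42)
fm <- feature_matrix(ds, max_order = 10)

ga <- gamma_analysis(fm[-(1:2)], fm$label, max_size = 3)
ga
#> Gamma-metric subset ranking: AF vs NSR (n = 130, 200)
#>  size  gamma  mode                subset
#>     1 1.1072 exact                 sd_d1
#>     2 3.3619 exact         mean_d3,sd_d2
#>     3 4.4982 exact mean_d0,mean_d2,sd_d1
#> Global best: gamma = 4.4982 with {mean_d0, mean_d2, sd_d1}

evaluate_split(fm[-(1:2)], fm$label, subset = ga$subsets[[2]], seed = 42)
#> <split_report> accuracy = 1.000 (train 264 / val 66) [non-converged fit]

duration_sweep(ds, durations = c(3, 5, 10, 30, 60),
               subsets = ga$subsets[2], seed = 42)
#> <duration_sweep> accuracy by observation window:
#>     mean_d3+sd_d2
#> 3s          0.824
#> 5s          1.000
#> 10s         1.000
#> 30s         1.000
#> 60s         1.000
```

Reading the output: the best single discriminator is the standard
deviation of a low-order derivative (`sd_d1`, the SD of heart-rate
velocity) rather than anything computed from the raw tachogram; a
two-variable γ-selected subset separates the hold-out set perfectly at
1 min (the `[non-converged fit]` tag marks complete separation, where
unpenalized maximum likelihood has no finite optimum — the
capped-iteration model is still a valid classifier); and accuracy
degrades gracefully, not catastrophically, as the observation window
shrinks toward 3 s.

A command-line wrapper over the same functions is installed at
`inst/cli/rrgamma` (subcommands `simulate`, `derive`, `features`,
`gamma`, `select`, `perturb`, `classify`, `sweep`; every run writes a
replay manifest).

## See also

The methods vignette (`vignettes/gamma-analysis.Rmd`) documents the
model assumptions, the synthetic-generator calibration, numerical
choices (ridge, tie-breaking, separation handling) and known
limitations.
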