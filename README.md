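# rtnoise

Reaction times collected in psychological experiments carry an additive
technical delay — keyboard and mouse polling, operating-system timer
granularity, browser timing — of roughly 10–100 ms per trial. `rtnoise`
quantifies what that delay does to *model-based* RT analyses: it simulates
clean data from an ex-Gaussian distribution or a two-boundary Wiener
diffusion model, contaminates a paired copy with per-trial uniform delays,
fits both versions by maximum likelihood, and summarises the induced bias
and its power cost. It is aimed at researchers who fit distributional RT
models (especially in browser-based experiments) and want to know which
parameters they can trust.

## Models and statistics

* **Ex-Gaussian**: the convolution of a normal(μ, σ²) and an exponential
  with mean τ (all ms); mean μ + τ, variance σ² + τ². Density evaluated in
  log space via the scaled normal tail so large σ/τ cannot overflow;
  fitting is Nelder–Mead ML on (μ, log σ, log τ) from moment-based starts.
* **Wiener diffusion**: evidence starts at z = a/2, drifts at rate v with
  within-trial coefficient s = 0.1, absorbs at 0 or a; observed
  RT = first-passage time + Ter. Across-trial variabilities are fixed at 0.
  The defective first-passage density/CDF use the standard
  small-time/large-time series with error-bounded truncation; fitting uses
  the toolbox-standard multinomial likelihood on the 0.1/0.3/0.5/0.7/0.9 RT
  quantiles per boundary (trial-level ML is available as `method = "ml"`),
  started from EZ-diffusion moment estimates.
* **Bias summary**: per parameter, OLS of noisy-data estimates on
  clean-data estimates across iterations; an intercept is "significant"
  when its 95 % CI excludes 0, a slope when its CI excludes 1. Noise-bound
  sweeps are summarised by weighted least squares with weights inversely
  proportional to the CI width.
* **Power cost**: paired t across simulated participants, converted to
  Cohen's d = t/√n, and the smallest n reaching 80 % power at two-tailed
  α = .05 from the noncentral t distribution.

See `vignettes/noise-and-parameter-recovery.Rmd` for the full methods
account, numerical choices, and known limitations.

## Worked example

Fit one 80-trial sample, then the same sample with U(10, 100) ms delays
added to every trial:

```r
library(rtnoise)
set.seed(2024)
rts <- rexgauss(80, mu = 500, sigma = 50, tau = 100)
fit_exgauss(rts)
#> Ex-Gaussian ML fit (n = 80 )
#>   mu = 505.06  sigma = 50.52  tau = 105.53
#>   logLik = -483.926  converged = TRUE
fit_exgauss(add_noise(rts, noise_spec(10, 100)))
#> Ex-Gaussian ML fit (n = 80 )
#>   mu = 563.17  sigma = 57.19  tau = 109.18
#>   logLik = -489.319  converged = TRUE
```

The delay (mean 55 ms) lands almost entirely in μ; σ and τ barely move.
The recovery pipeline makes that systematic — 100 iterations of
draw-parameters → simulate 80 trials → add noise to a copy → fit both,
then regression of noisy on clean estimates:

```r
rec <- run_recovery("exgauss", iterations = 100, seed = 1)
bias_summary_table(regress_noisy_on_clean(rec))
#>   parameter      term estimate ci_low ci_high        p significant
#> 1        mu intercept   46.578 17.678  75.478 1.86e-03        TRUE
#> 2        mu     slope    1.015  0.957   1.072 6.10e-01       FALSE
#> 3     sigma intercept   11.465  7.157  15.772 7.74e-07        TRUE
#> 4     sigma     slope    0.876  0.797   0.954 2.28e-03        TRUE
#> 5       tau intercept    2.340 -3.693   8.373 4.43e-01       FALSE
#> 6       tau     slope    0.987  0.928   1.046 6.71e-01       FALSE
```

Read: noise shifts μ̂ up by a constant (~47 ms here) independent of its
level (slope ≈ 1); it inflates σ̂ mostly when σ is small (positive
intercept, slope < 1); τ̂ is untouched. `autoplot(rec)` draws the
per-parameter scatter with the identity diagonal. The diffusion analogue is
`run_recovery("ddm", ...)`; the sweep over noise bounds is
`run_noise_sweep()`; the effect-size/power table is `run_simulation3()`.
Power arithmetic stands alone too:

```r
required_n(0.31)   # 84 participants for 80% power at alpha = .05
required_n(2.18)   # 4
```

A thin CLI over these functions lives at `inst/cli/rtnoise.R`
(`Rscript rtnoise.R sim1 --seed 1 --out results/`).

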