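# batchphys

Quantitative physiology of batch bioreactor cultivations: model-based
estimation of specific growth and substrate-uptake rates, off-gas CO₂
balancing, instantaneous carbon balancing with Gaussian error propagation,
and parametric Monte-Carlo bootstrap confidence intervals with
Latin-hypercube measurement perturbation.

Built for the workhorse experiment of microbial physiology — a stirred batch
reactor with biomass, residual d-glucose and off-gas O₂/CO₂ readings — and
for anyone who needs defensible specific rates (and error bars) out of it:
µ, π_GLC, π_CO₂ per strain, plus a check that the carbon books balance.

## The model

During exponential growth, biomass follows `X(t) = X0·exp(µ·t)` and, for a
constant specific uptake rate, glucose follows

```
c_GLC(t) = C − (π_GLC/µ) · X0 · exp(µ·t)
```

Both curves are fitted jointly by variance-weighted least squares over the
exponential-phase window, whose end is judged by the peak of the exhaust-gas
CO₂ fraction. The total CO₂ formation rate comes from an inert-gas balance
over the reactor gas phase, and the instantaneous carbon balance is

```
Θ = (µ·ω_C/M_C + π_CO₂) / (6·π_GLC)
```

with ω_C the carbon mass fraction of dry biomass (0.45 ± 0.05 gC/gCDW by
default) and M_C = 12.011 g/mol. Θ = 1 means all substrate carbon is
recovered in biomass and CO₂; aerobic glucose batches typically show Θ ≈ 0.8,
the gap being CO₂ dissolved as bicarbonate. Parameter uncertainty comes from
a parametric bootstrap (Latin-hypercube normal perturbation of every
in-window measurement, refit, percentile bounds; the default α = 0.25 gives
the interquartile range).

A synthetic batch generator (`simulate_batch()`) forward-simulates the same
model plus configurable noise and a dissolved-CO₂ retention fraction, so the
entire pipeline is testable without plant data.

## Worked example

```r
library(batchphys)

ds  <- simulate_batch(strain_preset(), noise_model(seed = 42),
                      n_points = 40, dt = 0.4)
w   <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
fit <- fit_rates(ds, w)
boot <- bootstrap_fit(ds, w, n = 200, seed = 42, fit = fit)
tidy(boot)
#> # A tibble: 4 × 6
#>   term    estimate  lower  upper      sd unit
#>   <chr>      <dbl>  <dbl>  <dbl>   <dbl> <chr>
#> 1 x0         0.110  0.108  0.113 0.00369 g/L
#> 2 mu         0.432  0.428  0.436 0.00573 h^-1
#> 3 pi_glc     4.95   4.88   5.01  0.0952  mmol gCDW^-1 h^-1
#> 4 c_const   57.0   56.6   57.4   0.577   mmol/L

gb <- offgas_balance(ds, fit, w)
cb <- carbon_balance(fit$mu, fit$pi_glc, gb$pi_co2_mean,
                     sd_pi_co2 = gb$sd_pi_co2_mean)
cb
#> <carbon_balance> theta = 0.7337 +/- 0.061
#>   biomass 54.6 % + CO2 18.8 % of uptake carbon; gap 26.6 %
```

The point estimates recover the preset's true physiology (µ = 0.45/h,
π_GLC = 4.82) to within a few percent at this noise level, and the bootstrap
intervals reflect it. The generator's default preset retains 20 % of
produced CO₂ in the broth (dissolved CO₂/bicarbonate), so the recovered Θ
sits below its full-closure value by ρ times the CO₂ share of uptake carbon
(plus estimation noise) — the mechanism behind the ~80 % closure seen in
real reactors. `autoplot(fit)`, `autoplot(boot)`, `autoplot(gb)` and
`plot_carbon_sinks()` draw the fit, the bootstrap sample and the stacked
carbon-sink bars; `run_pipeline()` chains the whole analysis from CSV files
and a YAML config, writing a tidy results table and a run log of every
constant used.

A reference table of published batch-reactor rates for a *C. glutamicum*
anaplerosis deletion panel ships with the package:

```r
r <- anaplerosis_rates()[1, ]  # wild type: mu 0.45, pi_glc 4.82, pi_co2 6.94
instantaneous_theta(r$mu, r$pi_glc, r$pi_co2)$theta
#> [1] 0.8229442
```

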