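# tempburden

Three-stage estimation of the mortality burden attributable to ambient
temperature, measured in **years of life lost (YLL)** — for environmental
epidemiologists running multi-city daily time-series analyses, and for
anyone who wants a fully testable reference implementation of the design.

The pipeline:

1. **Daily YLL construction.** Each death contributes the residual life
   expectancy e(age, sex) from a reference complete life table (two table
   editions can be averaged); per-day sums give the city's daily YLL series.
2. **City-level DLNM regression.** An identity-link Gaussian model of daily
   YLL on a temperature x lag *cross-basis*
   (quadratic B-spline in temperature with knots at the 27.5th/72.5th
   percentiles; natural cubic spline over lags 0–21), controlling for
   long-term trend and seasonality (natural cubic spline, 7 df/year),
   relative humidity, wind speed, sunshine duration and air pressure
   (3 df each), day of week, and holidays:

   YLL_t = α + β·cb_t + NS(t) + NS(RH_t) + NS(SD_t) + NS(WS_t) + NS(AP_t)
   + γ·DOW_t + δ·Holiday_t + ε_t

   The cross-basis block is reduced to the **overall cumulative
   exposure–response curve** η (4 coefficients) by summing the lag dimension.
3. **Multivariate meta-regression.** City curves are pooled under
   η_i ~ N(X_i μ, S_i + Ψ) by maximum likelihood; heterogeneity is
   quantified by Cochran Q and I² = max(0, (Q − df)/Q)·100, city-level
   meta-predictors are tested one at a time by 4-df Wald statistics with AIC
   model comparison, and per-city curves are shrunk to **BLUPs**.
4. **Attribution.** The minimum-YLL temperature (MMT) is found by 0.1 °C
   grid search; each day is assigned the curve difference between its
   temperature and the MMT (backward perspective, identity link), split into
   cold (below MMT) and heat (above); the **attributable fraction** is
   attributable YLL over total YLL, with 95% empirical confidence intervals
   from 1000 Monte Carlo draws of the curve coefficients.

A synthetic multi-city generator with a known smooth-V exposure–response
surface, known lag weights and an exact attributable-fraction oracle makes
the whole pipeline testable end to end; no registry data are required or
included (the shipped life table is synthetic and labelled as such).

## Worked example

```r
library(tempburden)

sim <- simulate_multicity(4, sim_config(), seed = 2024,
                          heterogeneity = "predictor")
series <- lapply(sim$cities, `[[`, "series")
res <- run_pipeline(series, meta = sim$meta,
                    predictors = "urbanization_rate",
                    n_mc = 1000, seed = 2024)
#> first stage [city01]: n_used=2536
#> ...
#> second stage: Q=27.90 (df=12, p=0.00573), I2=57.0%
#> third stage: pooled AF 6.69% (cold 3.17%, heat 3.52%)

res$attribution
#> attributable burden (n_mc=1000):
#>   AF total 6.69% (95% eCI 5.89 to 7.48)
#>   AF cold  3.17% (95% eCI 2.61 to 3.71)
#>   AF heat  3.52% (95% eCI 3.27 to 3.77)

res$heterogeneity[, c("predictor", "W", "W_p", "AIC", "Q", "Q_df", "I2")]
#>          predictor     W W_p    AIC     Q Q_df    I2
#>        (intercept)    NA  NA 190.42 27.90   12 56.98
#>  urbanization_rate 25.31   0 188.60  2.59    8  0.00
```

Reading the output: each city's 2557-day series loses 21 days of lag
burn-in (`n_used = 2536`). The intercept-only meta-analysis finds real
between-city heterogeneity (Q = 27.9 on 12 df, I² = 57%); adding the
urbanization-rate meta-predictor — which in this simulation truly drives
the between-city effect differences — absorbs it (Q drops to 2.6, I² to 0,
Wald W = 25.3 on 4 df) and improves the AIC. The pooled attributable
fraction of 6.69% (cold 3.17% + heat 3.52%, summing exactly) recovers the
generator oracle's true value of 6.86% for this draw; the cold/heat split
varies with each simulation's curve. The per-city minimum-YLL temperatures
are in `res$mmt` (here 15.8–17.8 °C).

A command-line wrapper with `simulate` and `run` subcommands is in
`inst/cli/tempburden.R`; a YAML config file (see `read_pipeline_config()`)
overrides the defaults, which reproduce the standard settings (lag 21,
knots at the 27.5th/72.5th percentiles, 7 df/year, 3 df covariates,
1000 Monte Carlo iterations).

## Package layout

- `R/life_table.R` — life tables, per-death YLL, daily aggregation
- `R/basis.R` — spline specifications, quantile knots, the cross-basis
- `R/first_stage.R` — design assembly, least-squares fit, curve reduction
- `R/meta.R` — multivariate ML meta-regression, Q/I², Wald, AIC, BLUPs
- `R/attribution.R` — MMT search, attributable YLL/fractions, Monte Carlo eCIs
- `R/synthetic.R` — the generator and its exact attributable-fraction oracle
- `R/io.R`, `R/pipeline.R` — CSV/YAML round-trip I/O and orchestration
- `vignettes/temperature-yll-burden.Rmd` — models, assumptions, design
  decisions and limitations
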