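# eibscale

Deciding whether a continuous treatment effect is **absolute** (a uniform
percentage-point shift) or **relative** (a proportional reduction), for
placebo-controlled cross-over trials of exercise-induced
bronchoconstriction (EIB).

In such trials every participant is exercise-challenged twice: the percent
fall in FEV1 is `X` after placebo and `D` after an inhaled beta2-agonist.
With the signed paired difference `Y = D − X` as response, three nested
linear mixed-effects models are compared by maximum likelihood:

```
Y = α + ε            intercept-only : one uniform absolute effect, −α pp
Y = α + β·X + ε
Y = β·X + ε          slope-only     : one proportional effect, −β·100 %
```

with crossed random intercepts/slopes per study and per drug (so each
likelihood-ratio step moves 3 parameters). Around this core the package
provides:

* participant-level effect arithmetic, stratified tables with
  multiplicatively symmetric ratio CIs (delta method on the log ratio),
  through-origin quantile-regression summaries (weighted quantiles of
  ratios) and skewness;
* regression-to-the-mean diagnostics: duplicate-placebo null slope,
  Blomqvist correction `(β_obs + r)/(1 − r)` with `r = s_w²/s_b²`, and the
  within-subject SD required to explain a slope by noise alone;
* study-level weighted mixed models and DerSimonian–Laird random-effects
  meta-analysis (Q, I², τ², Z) on the absolute scale and on two relative
  routes (normalization by the placebo mean; per-study through-origin
  slopes);
* a seeded synthetic cohort generator with the published trial pool's
  structure (14 studies, 187 participants, 6 drugs, proportional truth
  0.90), so every stage is testable against a known truth;
* `run_report()`, chaining everything into one reproducible JSON + text
  report.

## Worked example

```r
library(eibscale)

ipd <- simulate_ipd(simulation_config(seed = 42))   # 187 participants, 14 studies
fit_ipd_model(ipd, "slope_only")
#> Linear mixed-effects fit (ML): slope_only
#>   n = 187, engine = lmer
#>   relative effect: 94% of decline prevented (95% CI 89% to 99%)
#>   random-effect SDs:
#>     study_id:x             0.002
#>     drug:x                 0.044
#>   residual SD 7.98 pp, logLik -655.8, AIC 1319.7 (4 parameters)
```

The cohort was generated with a true proportional effect of 90%; the
slope-only model recovers it (94%, CI 89–99%). Comparing the three models:

```r
f1 <- fit_ipd_model(ipd, "intercept_only")
f2 <- fit_ipd_model(ipd, "intercept_and_slope")
f3 <- fit_ipd_model(ipd, "slope_only")
compare_fits(f1, f2)
#> LRT: intercept_only vs intercept_and_slope
#>   chi2 = 266.82 on 3 df, p = 1.5e-57, delta AIC = 260.82
compare_fits(f3, f2)
#> LRT: slope_only vs intercept_and_slope
#>   chi2 = 0.23 on 3 df, p = 0.973, delta AIC = -5.77
```

Adding the slope to the intercept model improves the fit enormously;
removing the intercept from the full model costs nothing. The slope-only
(relative) description wins, and its median absolute residual is 5.5 pp
against 9.5 pp for the uniform-shift model. The regression-to-the-mean
diagnostic confirms the slope is not a noise artifact:

```r
rtm_diagnostic(ipd, f2$beta)
#> Regression-to-the-mean diagnostic
#>   duplicate-placebo pairs: 62
#>   within-subject SD:  6.12 pp
#>   between-subject SD: 17.71 pp
#>   null (placebo-placebo) slope: -0.089
#>   observed slope -0.925 -> Blomqvist-corrected -0.914
#>   within-subject SD required to produce the slope: 58.2 pp
#>   verdict: negligible
```

Study-level pooling of the per-study through-origin slopes gives a pooled
relative effect of 95% (I² = 45%, Z = 41.7):

```r
pool_random_effects(to_relative_by_slope(ipd))
```

`run_report(pipeline_config(sim_config = simulation_config(), seed = 42))`
runs all of the above plus the stratified table, distribution summaries and
the three meta-analyses in one call.

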