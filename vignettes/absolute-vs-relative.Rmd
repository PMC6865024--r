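---
title: "Absolute or relative? Choosing the scale of a continuous treatment effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute or relative? Choosing the scale of a continuous treatment effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eibscale)
```

## The problem

Inhaled beta2-agonists protect against exercise-induced bronchoconstriction
(EIB), measured as the percent fall in FEV1 after a standardized exercise
challenge. In a placebo-controlled cross-over trial each participant is
challenged twice — once after placebo (decline $X$, in percentage points,
positive when FEV1 fell) and once after the drug (decline $D$) — so the drug
effect is a within-person paired contrast. It can be summarized two ways:

* **absolute scale**: the drug removes a fixed number of percentage points
  of decline, the same for everyone ($X - D$ is constant);
* **relative scale**: the drug prevents a fixed *proportion* of each
  person's untreated decline ($1 - D/X$ is constant).

The distinction matters clinically: a 20 pp uniform benefit overstates the
effect for a mild patient with a 12% decline and understates it for a severe
one with a 60% decline. This package implements the machinery for deciding
which description fits cross-over IPD better, together with the study-level
analyses a meta-analyst would run when only summary data are available.

## The model comparison

With the signed paired difference $Y_i = D_i - X_i$ as response, three
nested linear mixed-effects models are fitted by maximum likelihood:

$$Y_i = \alpha + \varepsilon_i \qquad\text{(intercept-only, absolute scale)}$$
$$Y_i = \alpha + \beta X_i + \varepsilon_i$$
$$Y_i = \beta X_i + \varepsilon_i \qquad\text{(slope-only, relative scale)}$$

A helpful drug gives $\alpha < 0$ (reported to users as $-\alpha$ pp of
decline prevented) and $\beta < 0$ (reported as $-\beta \times 100$ percent
of the decline prevented). Trials differ in drug, challenge protocol and
population, so the trial and the drug type act as crossed clustering
variables: every fixed term carries two independent random counterparts —
random intercepts per study and per drug for $\alpha$, random slopes
(without intercepts, uncorrelated) per study and per drug for $\beta$.
Moving between adjacent specifications therefore changes one fixed effect
and two variance components at once, which is why the likelihood-ratio
tests run on 3 degrees of freedom. ML (not REML) is used throughout so
log-likelihoods and AIC are comparable across fixed-effect structures; the
price is the usual small downward bias in variance components, which is
irrelevant to the comparison itself.

```{r ipd-fits}
ipd <- simulate_ipd(simulation_config(seed = 7))
fits <- lapply(c("intercept_only", "intercept_and_slope", "slope_only"),
               function(s) fit_ipd_model(ipd, s))
names(fits) <- c("intercept_only", "intercept_and_slope", "slope_only")
fits$slope_only
compare_fits(fits$intercept_only, fits$intercept_and_slope)
compare_fits(fits$slope_only, fits$intercept_and_slope)
```

Model adequacy is also summarized by the median absolute conditional
residual (`median_abs_residual()`), i.e. including predicted random
effects. Marginal residuals would be a defensible alternative; conditional
residuals were chosen because the question is how well each *fitted* model
tracks individual participants.

## Participant-level statistics

`absolute_effect()` and `relative_effect()` implement the per-participant
arithmetic ($X - D$, and $(X - D)/X$). Participants with $X \le 0$ (FEV1
rose after placebo exercise) have no meaningful relative effect; they are
excluded from relative-scale participant summaries but retained in all
absolute-scale and model-based analyses.

`stratify_by_placebo_decline()` bins participants by $X$ (closed-open
bins $[l, h)$, final bin closed at the observed maximum; records below the
first edge excluded, default edge 10 pp — the conventional EIB threshold).
Within each stratum the absolute effect gets a paired t-interval, and the
relative effect is the ratio of means $\overline{X-D}/\overline{X}$ with a
delta-method CI on the log ratio, exponentiated back — hence
multiplicatively symmetric (`high/point = point/low`). Because IPD is in
hand, the numerator-denominator covariance is included by default;
`include_covariance = FALSE` gives the summary-data variant, and comparing
the two shows how much the covariance term matters.

`quantile_relative_effect()` summarizes the distribution of relative
effects as through-origin quantile-regression slopes of $X - D$ on $X$.
For one positive covariate the check-loss minimizer over through-origin
lines is exactly the $|X|$-weighted quantile of the per-participant ratios,
and it is computed that way (the lowest breakpoint at which the cumulative
weight crosses $q \sum w$; ties toward the smaller slope). Large declines
thus carry more weight, which is what distinguishes these summaries from
plain quantiles of the ratios. `skewness()` uses the unadjusted moment
estimator $m_3/m_2^{3/2}$ by default (`adjusted = TRUE` applies the
$\sqrt{n(n-1)}/(n-2)$ correction); the choice is stated because the two
differ visibly at $n$ near 150.

## Regression to the mean

A negative slope of change on baseline can be an artifact: with test-retest
noise $s_w$ and observed between-subject SD $s_b$, a null comparison
already shows a slope of $-s_w^2/s_{b,\text{true}}^2$-type attenuation.
Three diagnostics are provided (`rtm_diagnostic()` runs all of them):

1. the observed slope of a duplicate placebo test on the first placebo test
   (`rtm_observed_slope()`), which estimates the pure regression-to-the-mean
   slope;
2. the Blomqvist correction
   $\beta_{\text{true}} = (\beta_{\text{obs}} + r)/(1 - r)$ with
   $r = s_w^2/s_b^2$ (`blomqvist_correct()`);
3. the within-subject SD that would be needed for regression to the mean
   alone to generate the observed slope (`required_within_sd()`), solved
   from $s_w^2 = |\beta| s_{b,\text{true}}^2 / (1 - |\beta|)$ with
   $s_{b,\text{true}}^2 = s_b^2 - s_w^2$.

Conventions worth stating: $s_w$ comes from the duplicate-test subset while
$s_b$ is computed over *all* participants' placebo declines — the
asymmetry is deliberate, since the duplicate subset is small. For the
required-SD computation two natural conventions exist (hold the observed
$s_b$ fixed, or hold the true between-subject SD fixed); the second is
implemented because the thought experiment varies the noise while the
population stays the same. The verdict is "negligible" when correction
changes the slope by less than 10% — an interpretation threshold, not a
test.

## Study-level analysis and meta-analysis

`aggregate_to_study_level()` produces the summary a trial report would
give: $n$, mean declines, mean paired difference and its SE
($\mathrm{SD}/\sqrt n$). `fit_study_level_models()` runs the same three
specifications on study means with random terms by drug only and case
weights per study. The weighting of study means is genuinely ambiguous in
practice — both $n$ and $\sqrt n$ weighting are defensible and both are
implemented (`weight_scheme`); `run_report()` fits both and surfaces the
alternative's headline numbers so the disagreement is visible rather than
hidden. `sqrt_n` is the default.

For standard meta-analysis, three per-study effect routes feed
`pool_random_effects()`:

* `to_absolute_effect()`: $-\overline{Y}$ with its paired SE (pp);
* `to_relative_by_normalization()`: the absolute effect and SE divided by
  the study's mean placebo decline — possible with summary data only;
* `to_relative_by_slope()`: the through-origin OLS slope of $Y$ on $X$ per
  study (IPD required), usually with smaller SEs. `intercept = TRUE` gives
  the with-intercept variant for sensitivity.

Pooling is DerSimonian-Laird generic inverse variance: fixed weights
$w_j = 1/se_j^2$, $Q = \sum w_j(\theta_j - \bar\theta_w)^2$,
$\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\}$, then
random-effects weights $1/(se_j^2 + \tau^2)$, with z-based symmetric CIs
(no Knapp-Hartung, matching standard generic-inverse-variance software) and
$I^2 = \max\{0, (Q - df)/Q\}$. Relative effects are pooled on the plain
proportion scale — both relative routes produce symmetric CIs by
construction — rather than on a log-ratio scale; a log-scale analysis can
be run by transforming the estimate table before pooling.

```{r meta}
st <- aggregate_to_study_level(ipd)
pool_random_effects(to_relative_by_slope(ipd))
```

## The synthetic cohort generator

`simulate_ipd()` exists so the full pipeline is testable against a known
truth. Its generative model is proportional on purpose — the slope-only
model is the true model, making parameter recovery well-posed:

$$X_i = T_i + e_{w,i}, \qquad
  D_i = T_i(1 - \rho_s) + e'_{w,i} + e_{r,i}, \qquad
  \rho_s = \rho + u_{\text{study}} + v_{\text{drug}},$$

with $T_i$ a truncated lognormal true decline whose log-location is shifted
per study. The defaults encode the published trial pool's conditions: 14
studies with the published per-trial sample sizes (187 participants), 6
drug types assigned many-to-one, $\rho = 0.90$, within-subject SD
6.23 pp, and a baseline distribution (meanlog $\log 31$, within-study
sdlog 0.51, study-level location SD 0.40, truncation 5-85 pp) calibrated
once so the marginal placebo-decline distribution matches the published
median ($\approx 31$ pp), between-subject SD ($\approx 18.9$ pp) and range,
and so the between-trial heterogeneity of absolute effects is high
($I^2 \approx 0.8$), as observed across the real trials, which differed
markedly in severity. The cluster slope SDs (0.05 each) and the extra
residual SD on the drug test (6 pp) are stated defaults, not published
quantities — the source analysis reports no cluster variance components.
A configurable fraction of studies (default 4/14) contributes a duplicate
placebo test for the regression-to-the-mean diagnostics.

What the generator deliberately does **not** emulate: any dependence of the
individual relative effect on the baseline decline (in the real data the
two correlate — relative effects shrink and skew left at small declines —
which is why the real pool's intercept-only estimate, normalization-route
pooled effect and lower quartile sit below what a purely proportional
truth produces); digit preference and measurement rounding; drop-out; and
any per-trial protocol differences beyond the cluster deviates. Passing
tests on this cohort therefore demonstrate that the estimators recover a
known proportional truth under realistic noise and clustering — not that
the real data were proportional; that conclusion belongs to the original
analysis of the real IPD.

## Numerical choices and degenerate inputs

* Percent declines live on the 0-100 pp scale in files and objects;
  relative effects are proportions (0-1) everywhere except human-readable
  printouts, preventing percent/proportion confusion.
* Grouping factors with fewer than two levels are dropped with a warning;
  with no random term left the fit degrades to (weighted) least squares,
  so single-study data remain analyzable.
* Singular variance components are flagged (`boundary`) rather than
  treated as errors; fully degenerate zero-residual fits return `NA`
  standard errors.
* LRT statistics are clipped at zero; weighted quantiles break ties toward
  the smaller slope; truncation in the generator is by rejection sampling.
* Studies with $n < 2$ (undefined paired SE), zero SEs in pooling
  (continuity adjustment required), mixed scales in one pooling call, a
  zero placebo decline in a relative effect, and $s_w \ge s_b$ in the
  Blomqvist correction are all hard errors with instructive messages.

## Problem sizes used by the test suite

The suite relies on fixtures of three sizes, chosen to keep every check
sharp at desk scale: hand instances of 2-10 records for exact oracles,
cohorts of the default published dimensions (187 participants, 14 studies)
for pipeline checks and parameter recovery across 20 replicate seeds, and
$10^4$-participant draws for Monte-Carlo comparisons against closed forms
(null-effect mean and the regression-to-the-mean attenuation slope).

## Known limitations

* The mixed models assume homoscedastic residuals; the real paired
  differences are likely more variable at large declines.
* The through-origin quantile summaries assume all included declines are
  positive (enforced via `min_placebo_decline`).
* DerSimonian-Laird $\tau^2$ is a moment estimator; REML/Paule-Mandel
  alternatives are not provided.
* No imputation: studies lacking a paired SE must be excluded before
  pooling.
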