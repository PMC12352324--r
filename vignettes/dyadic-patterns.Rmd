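---
title: "Dyadic patterns of stress and depression: the APIM, the ratio k, and how dyadik estimates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic patterns of stress and depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Couples are not independent observations. When both partners of a dyad are
measured on a predictor (here prenatal stress, PSS-14 totals) and an outcome
(prenatal depression, EPDS totals), each person's outcome may depend on their
own predictor (the *actor* effect, `a`) and on their partner's predictor (the
*partner* effect, `p`). The Actor-Partner Interdependence Model (APIM) fits
both at once on four observed variables:

$$y_1 = a_1 x_1 + p_{12} x_2 + e_1, \qquad y_2 = p_{21} x_1 + a_2 x_2 + e_2,$$

with `x1, y1` the woman's stress and depression, `x2, y2` the husband's,
`cov(x1, x2)` free (partners share an environment) and `cov(e1, e2)` free
(outcomes share unmodelled causes). Ten parameters reproduce the ten unique
moments of `(x1, x2, y1, y2)`, so the unrestricted model is *saturated*:
it fits any sample covariance exactly.

The scientific question is not the individual paths but their ratio
`k = p / a`. Three values of `k` name the interesting regimes: `k = 0`
(actor-only: your stress affects only your own depression), `k = 1`
(couple-oriented: actor and partner effects equal), `k = -1` (contrast:
equal magnitude, opposite sign). `dyadik` estimates `k` directly, bootstraps
its confidence interval, and walks a decision flowchart to name the pattern.

# Estimation

## Maximum likelihood on moments

`fit_apim()` minimizes the normal-theory discrepancy

$$F = \log|\Sigma(\theta)| - \log|S| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1}) - 4$$

over the free parameters, where `S` is the sample covariance (or
correlation) matrix. `chi2 = (N - 1) * F` by default; the `N` convention is
available (`scaling = "N"`). A correlation matrix is treated as the
covariance matrix of standardized variables, so its estimates are
standardized estimates. Three solution routes are used, in order of
preference:

* **Closed form** for the saturated model: two two-predictor regressions on
  the moments plus the empirical residual covariance. `F = 0` exactly.
* **Concentrated likelihood** whenever every (co)variance parameter is free:
  the ML solution necessarily sets the exogenous block to the sample block
  and the residual block to the empirical residual covariance of the fitted
  paths, which makes `tr(S Σ⁻¹) = 4` exactly and reduces the problem to
  minimizing `log det Ψ̂(B)` over the path (or ratio) parameters alone —
  two or three dimensions instead of eight to ten. All fits on the
  replication path (equality constraints, ratio ties, `k` fixed at
  0 or ±1) take this route.
* **Generic BFGS** on the full free vector for anything else (e.g. the
  stricter variance-equality variant of distinguishability), started at the
  saturated closed form, with non-positive-definite proposals penalized.

Convergence is declared when a restart from the optimum moves `F` by less
than 1e-8; `F` is clamped at zero against numerical noise (analytically
`F >= 0`, with equality iff the implied moments reproduce `S`).

## The ratio-tied (phantom) parameterization

`k` could be computed as `p̂/â`, but `dyadik` estimates it as a parameter:
`apim_spec(ratio_k = "two")` replaces the partner paths by `p12 = k1 a1`,
`p21 = k2 a2` (the phantom-variable construction). For the unrestricted
model this is a pure reparameterization — the fit is preserved exactly, a
property the test suite asserts — and it is what makes "fix `k` at 0, 1 or
-1 and refit" a well-defined operation. The default pairing is
`k1 = p12/a1`, `k2 = p21/a2` (each partner's *incoming* partner path over
their own actor path, the convention in which the published pair of ratios
{0.059, 0.064} is recovered from the published correlations); the
*outgoing* pairing is available via `convention = "outgoing"`.

Because a ratio explodes when its denominator vanishes, `k` is refused
whenever a required standardized actor effect is below 0.10 in magnitude
(`guard` argument).

## Bootstrap confidence intervals

Confidence intervals are 95% percentile bootstrap (default `B = 5000`,
`seed` mandatory). With raw dyads, couples are resampled with replacement
and the saturated model refitted in closed form per replicate. With only
summary moments, a parametric bootstrap draws `n` multivariate-normal rows
from the moment matrix — the only resampling available without raw data,
and an approximation that assumes normality. Replicates that violate the
actor guard or fail to converge are dropped and counted; more than 5%
dropped raises a warning. Replicates are never redrawn, so `B` keeps its
interpretation.

# The decision flowchart

`classify_pattern()` follows the four-step procedure:

1. Fit the saturated APIM.
2. Test distinguishability: constrain `a1 = a2` and `p12 = p21` and compare
   by likelihood ratio. Partners are treated as indistinguishable when
   `p >= 0.2` (a deliberately liberal threshold — wrongly pooling
   distinguishable partners biases estimates, wrongly splitting only costs
   efficiency). Indistinguishable dyads get a single common `k` from the
   equal-effects model.
3. For distinguishable dyads, estimate `k1` and `k2` and test `k1 = k2` by
   LR. A non-significant difference (default alpha 0.05) collapses the two
   ratios to a single common `k` (actor effects still free) whose bootstrap
   CI drives the decision. This collapse is part of the flowchart, not an
   optimization: two separate 95% intervals jointly cover their target only
   ~90% of the time even when the procedure is correct, so skipping the
   collapse (available via `collapse_equal = FALSE`) systematically
   over-rejects the simple patterns.
4. Check the active CI against the critical values. If it covers 0 but not
   ±1, refit with `k` fixed at 0; adequate fit → actor-only, inadequate →
   none. Same logic for 1 (couple) and -1 (contrast). A CI covering both 0
   and a unit value reports both candidate refits as `ambiguous`. Every
   branch is recorded in a decision trace.

"Adequate fit" means all five conventional thresholds simultaneously:
`chi2/df < 3`, `CFI >= 0.90`, `TLI >= 0.90`, `RMSEA <= 0.08`,
`SRMR <= 0.08` (`fit_thresholds()`). The baseline for CFI/TLI is the
independence model (all covariances zero, variances free), which has the
closed form `F = -log det R` with 6 df. CFI truncates excess chi-square at
zero; TLI is deliberately not truncated and exceeds 1 for models that fit
better than their df (the replication reproduces TLI ≈ 1.01 for the
`k = 0` model). RMSEA uses the same `N - 1` scaling as the chi-square.
SRMR is the root mean square of the 10 unique correlation-scale residuals,
diagonal included (those residuals are zero whenever variances are free).
The partner-only pattern (`a = 0`, `p ≠ 0`) is excluded from the flowchart
as empirically rare; `allow_partner_only = TRUE` reports the
actor-paths-fixed-to-zero refit for expert review.

# The synthetic-couple generator

`generate_dyads()` draws couples from the linear path system on z-scaled
predictors with configurable actor paths, partner paths, stress
cross-correlation `rho_x`, residual correlation `rho_e`, and scale/location
parameters; residual scales default to whatever makes the outcomes
unit-variance, so the paths are standardized coefficients.
`implied_population_moments()` gives the exact population covariance
(e.g. `r(x2, y1) = p12 + a1 rho_x`), used both for closed-form oracles and
for parameter-recovery checks. Presets (`sim_scenario()`): `paper_like`
(paths fitted from the packaged correlation matrix, which the implied
moments then reproduce to 1e-6), `actor_only` (a = 0.5, p = 0), `couple`
(a = p = 0.4), `contrast` (a = 0.4, p = -0.4), all with `rho_x = 0.212`
and `rho_e = 0.16` — the values implied by the reference study's own
moments — and n = 282 dyads. These were fixed once, from the study, not
adjusted afterwards.

What the generator emulates: the correlational structure the APIM assumes,
exactly. What it does not: bounded integer scale totals (it draws Gaussian
variables; `discretize = TRUE` optionally rounds and clips for
stress-testing), item-level measurement error, missingness, covariate
confounding. Passing tests therefore certify the estimator and the decision
procedure under the model's own assumptions, not robustness to real-data
violations of them. Item-level responses for exercising the scoring layer
are generated exactly uniformly over all item vectors consistent with a
given total (dynamic-programming sampling, no rejection), with PSS-14
reverse keying honoured.

# Numerical and design choices

* **Reverse-keyed PSS-14 items**: positions 4, 5, 6, 7, 9, 10, 13 (the
  instrument's standard positive-item set), configurable because published
  translations differ. EPDS input is assumed already severity-oriented
  (0-3), with an optional reverse set. Missing items are refused, never
  imputed.
* **Chi-square tests** on role-by-category tables are uncorrected Pearson
  (df = 1); Yates correction is off by default (the published worked
  examples reproduce only without it) and available as an option. A McNemar
  variant exists for genuinely paired use but is off the replication path,
  which mirrors the common unpaired presentation.
* **Wilcoxon signed rank**: zero differences dropped before ranking,
  mid-ranks for ties, tie-corrected variance, two-sided normal
  approximation. Checked against full sign enumeration up to n = 12.
* **Stress-by-gender interaction**: identity-link least squares with CR0
  cluster-robust standard errors clustered on dyad (partners are not
  independent observations).
* **Plain ML, not robust ML**: robust corrections need raw-data fourth
  moments, which summary moments cannot supply; bootstrap inference covers
  non-normality on the k scale. This is a documented deviation from the
  reference analysis and one reason its printed chi-square (0.949) is
  flagged rather than matched (the package's ML value on the same moments
  is 0.957; the source's own text and table additionally disagree with each
  other on chi2/df, 1.423 vs 0.475).
* **Degenerate inputs**: non-positive-definite moment matrices, zero
  margins, constant variables, all-zero paired differences and zero
  total-score variance are refused with diagnostics rather than patched.

# Problem sizes used by the validation suite

The suite's stochastic checks run at the study's own scale, n = 282 dyads:
per-CI bootstrap coverage of `k` at true `p = 0` over 1,000 generated
samples (B = 500 per sample); pattern recovery over 400 samples per preset
(B = 500), with the routing fixed to the single-common-k branch because the
preset populations are exchangeable across partners — that branch *is* the
correct route, and fixing it isolates the classifier from the
distinguishability screen's deliberately liberal 20% type-I rate (running
the full inferential chain instead yields recovery around 0.88-0.91, the
misrouted fifth of samples then entering the two-separate-CI flow whose
joint coverage is necessarily below nominal); parameter-recovery bias over
500 samples against 3 Monte-Carlo standard errors; generator moment checks
at n = 100,000. These sizes are the package's accuracy/runtime compromise;
the estimators themselves have no embedded limits.

# Known limitations

* Moments-only input cannot support nonparametric resampling; its
  bootstrap is parametric-normal and inherits that assumption.
* No mean structure, latent measurement models, missing-data FIML, or
  multiple-imputation sensitivity analysis.
* The distinguishability decision constrains paths only by default;
  variance equality is available (`include_variances = TRUE`) but is not
  the replication convention.
* With `B` in the low hundreds the percentile bounds carry visible
  Monte-Carlo noise; the default `B = 5000` is recommended for reporting.
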