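---
title: "Methods: from benefit rules to child overweight prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from benefit rules to child overweight prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bmisim links three stages: a rule-based benefit engine acting on household
disposable income, a chain of seven concatenated child-growth regressions
driven by log equivalised income, and a Monte Carlo projection of
overweight and obesity prevalence under counterfactual policy scenarios.
This vignette explains the model, its assumptions, and the numerical and
design choices behind the implementation.

## The income exposure

Household disposable income (euros/month) is equivalised by the
OECD-modified scale: 1.0 for the first adult (member aged 14+), 0.5 for
each further member aged 14+, 0.3 for each member under 14. The exposure
entering every growth regression is the **EHII**, the natural log of
equivalised disposable income. Benefit scenarios only ever add income, so
counterfactual EHII is never below baseline.

The nine built-in scenarios pair a universal basic income (BI), a
poverty-reduction transfer (PR), a new-borns benefit (NB) and a child
benefit (CB) each at a yearly and a monthly intensity of the same
per-payment amount, against a zero-cost baseline (BS). Eligibility for the
targeted scenarios is a strict `< 500` euros/month test: on a per-capita
basis (income / household size) for PR, on an equivalised basis for NB and
CB, following the respective policy definitions; both bases can be
overridden per scenario. Eligibility is assessed once on baseline income —
the simulation is a single-pass static one, with no benefit withdrawal,
taxation of benefits, or behavioural response. A yearly payment is spread
uniformly (amount/12) into the monthly accounting.

## The growth chain

Seven linear regressions are concatenated so that each outcome depends on
the two preceding outcomes (the first on none, the second on one), on
EHII, and on three shared covariates: maternal age at delivery, maternal
country of birth (0 = Italy, 1 = other) and child sex (0 = male,
1 = female):

$$
\begin{aligned}
GA &= \alpha_1 + \delta_1\,\mathrm{EHII} + \textstyle\sum\beta_{1s}X_s + \varepsilon_1\\
BW &= \alpha_2 + \beta_2\,GA + \delta_2\,\mathrm{EHII} + \textstyle\sum\beta_{2s}X_s + \varepsilon_2\\
&\ \ \vdots\\
BMI_{120} &= \alpha_7 + \beta_{7a}\,BMI_{84} + \beta_{7b}\,BMI_{48}
  + \delta_7\,\mathrm{EHII} + \textstyle\sum\beta_{7s}X_s + \varepsilon_7
\end{aligned}
$$

with outcomes gestational age (weeks), birth weight, weight at 6 and 18
months, and BMI at 48, 84 and 120 months. The total income effect on any
outcome is the chain-rule accumulation over all paths
(`income_effect_gradient()`); for BMI at 120 months it is ≈ −1.43 BMI
units per log-income unit under the packaged coefficients, and the package
verifies this against a finite-difference probe of the noise-free chain.

**Units.** All internal weights are in hectograms. The packaged
coefficient table is only internally consistent on that scale (for
example, the birth-weight equation evaluated at mean gestational age gives
≈ 36 hg ≈ 3.6 kg, and the weight-at-18-months mean plug-through lands at
≈ 11.2 kg), although weights are conventionally *printed* in grams; the
CSV interfaces therefore accept grams and convert.

## The packaged coefficient preset

`table3_parameters()` returns the chain preloaded with the published point
estimates, per-equation sample sizes and $R^2$. Standard errors are
recovered from the printed 95% CIs as half-width / 1.96, and each
equation's residual scale as the marginal outcome SD times
$\sqrt{1 - R^2}$.

Only *marginal* SEs are published. Their joint distribution matters: in an
OLS fit the intercept is strongly anticorrelated with the slopes, and the
variance of the predicted mean at the covariate mean is $\sigma^2/n$ —
orders of magnitude below what independent draws of intercept and slopes
would imply. Sampling the preset with a diagonal covariance therefore
produces wildly unstable prevalences (the intercept SE of the last
equation alone is 2.86 BMI units). The default (`vcov = "design"`)
rebuilds each equation's coefficient **correlation** matrix from the OLS
information matrix $(X^\top X)^{-1}$ of a fixed-seed reference cohort
drawn from the packaged covariate distributions, and scales it by the
published SEs. Every published marginal SE is preserved exactly while the
predicted-mean variance returns to its natural scale. `"diagonal"` is
retained as an option for sensitivity analyses.

## Synthetic population and cohort generators

Both data sources behind the model are restricted-access, so the package
generates survey-like stand-ins whose *marginal* statistics match the
published baseline table.

The household generator draws, per household: 1–3 children (probabilities
0.4/0.4/0.2), a second adult with probability 0.8, integer child ages
uniform on 0–13 with at least one under 5 imposed at generation (the
standard sample restriction — at most 7 members, at least one child under
5 — is thus satisfied by construction but remains available and tested as
an operation), maternal age at delivery N(33.6, 5.2²) truncated to 16–50,
a foreign-born mother with probability 0.168, a 51.6% female share among
children, and log-normal survey weights. Income is drawn at the
*equivalised* level as exp N(7.02, 0.67²) euros/month and multiplied by
the equivalised size, so the log equivalised income distribution hits its
target by construction regardless of composition. The published table
gives no joint composition–income structure, so composition and income are
independent by assumption — a limitation surfaced in the configuration.

Children under 5 are expanded to a weighted study population of 30,910
records by largest-remainder apportionment of the survey weights, which
conserves the total exactly and is deterministic.

The cohort generator draws covariates from the cohort's marginals (EHII
N(7.38, 0.26²), maternal age N(33.3, 4.4²), 4.2% foreign-born, 49.3%
girls) and generates outcomes sequentially from the chain plus Gaussian
residuals. Missingness can be layered per outcome to mimic the declining
follow-up of a dynamically recruited cohort; fitting is per-equation
complete-case, so equation sample sizes decline accordingly.

What the generators do **not** emulate: the real income distribution's
heavy left tail and its correlation with household composition, regional
and seasonal structure, within-mother clustering of pregnancies, and
informative missingness. Passing tests demonstrate correctness of the
machinery and reproduction of the published aggregate behaviour under
these idealised marginals, not validity on real microdata.

## Monte Carlo projection

Each run draws one coefficient vector per equation from a multivariate
normal around the point estimates with the equation's covariance
(independent across equations), plus one Gaussian residual per child per
equation. Residual draws at the individual level are essential: without
them the simulated BMI distribution collapses to the covariate-driven
spread (~1 BMI unit) and essentially no child crosses an obesity cut-off.
The narrow SDs of reported *simulated* baselines are read as across-run
SDs of means, consistent with this choice.

Runs are paired across scenarios by **common random numbers**: run seeds
are pre-drawn from the master seed, and both the parameter draw and the
residual stream are generated once per run, before the scenario loop.
Identical scenarios therefore give per-run prevalence ratios of exactly 1,
and scenario contrasts are free of between-run noise. A consequence worth
noting: with parameters fixed at their point estimates every BMI outcome
has a negative total income gradient, so benefits can only lower per-run
prevalence; under parameter draws an occasional run samples a positive
income effect and the ratio exceeds 1 in that run — which is why interval
upper bounds can exceed 1.

**Calibration.** Because the estimating cohort is not nationally
representative, the first two intercepts are calibrated: the
gestational-age intercept against a premature-birth prevalence target
(GA < 37 weeks) and then the birth-weight intercept against a mean
birth-weight target, each by golden-section minimisation of the squared
error over ±5 outcome units (tolerance 1e−6). The premature share is
computed analytically as `mean(pnorm((37 − mu_i)/sigma_1))`, integrating
the residual rather than simulating it, so calibration is deterministic
and idempotent. The packaged default targets are synthetic registry
stand-ins derived from the simulated baseline (mean birth weight 3218 g;
premature share `pnorm((37 − 39.6)/1.8)` ≈ 7.4%); users with access to
real registry values should supply them via `calibration_targets()`.

**Classification.** BMI at 48, 84 and 120 months is classified with the
published IOTF age- and sex-specific cut-offs (packaged as a plain-text
CSV, user-overridable), boundary inclusive. Overweight *includes* obesity
by default — the standard IOTF reporting convention — with a switch
because either reading is defensible.

## Reporting

Per-run prevalence ratios use the scenario as numerator and the baseline
as denominator; the point estimate is the mean of per-run ratios and the
interval their 2.5th/97.5th percentiles (the only computable reading of a
"prediction interval" over Monte Carlo runs). The percentage-point
reduction is derived from the PR point, `100 · p_BS · (1 − PR)`, which
keeps the two internally consistent. The marginal cost divides the
**annual** national scenario cost — survey weights scaled so the sample
represents 60.6 million residents — by that reduction; a non-positive
reduction is reported as the sentinel `NC`, not infinity. Annual (rather
than cumulative) cost is an explicit, configurable assumption; it
reproduces the published order of magnitude (a ~€6 billion/year universal
benefit against a ~0.3 pp reduction gives ~€2 × 10^10 per pp). Density
figures use Gaussian kernels with Silverman's bandwidth.

## Problem sizes and determinism

The reference protocol uses 1000 runs; the packaged analyses and tests use
200 runs on the full 30,910-child population, at which the PR point
estimates are stable to well under 0.005 — consistent with the published
stability criterion for choosing the run count. Every stochastic stage
takes an explicit seed; per-run seeds are pre-drawn so results are
reproducible and scenario-paired regardless of execution order. The
test-suite parameter-recovery study uses 200 replicated cohorts of
n = 5000 and checks nominal 95% coverage of each income coefficient
within [90%, 99%].

## Known limitations

- Associations in the growth chain are observational; the projection
  inherits any residual confounding.
- Income is held fixed over each child's whole trajectory; there is no
  household ageing, migration or policy phase-in.
- The marginal-cost division is not a cost-effectiveness analysis and
  should not be read as one.
- Full-chain trajectories (gestation through age 10) are simulated for all
  expanded children under each scenario; re-simulating birth outcomes for
  children already born at policy time is a deliberate simplification of
  an ambiguous protocol choice.
- Coefficient draws are independent across equations; any cross-equation
  estimation covariance is ignored.
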