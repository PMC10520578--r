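---
title: "Marginal structural models for income-mediated effects of unemployment on mental health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural models for income-mediated effects of unemployment on mental health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmmed)
```

## The scientific problem

Losing paid work damages mental health, and it also lowers household
income -- itself a determinant of mental health. For policy the split
matters: the part of the unemployment effect that runs through income
could be offset by income-protection policies, while the remainder
could not. `msmmed` estimates, from a long-format person-by-wave panel:

* the **total effect (TE)** of non-employment on common mental disorder
  (CMD; GHQ-12 score $\ge 4$), including any pathway through income;
* the **controlled direct effect (CDE)**, the effect remaining once the
  contemporaneous income pathway is blocked; and
* the **percentage mediation** $100 \times (\mathrm{TE} -
  \mathrm{CDE})/\mathrm{TE}$, with person-clustered bootstrap
  confidence intervals.

Both effects are estimated with double-robust marginal structural
models: stabilised inverse-probability-of-treatment weights (IPTWs)
make exposed and unexposed person-waves exchangeable with respect to
the measured adjustment set, and the weighted pooled logistic outcome
model adjusts for the same covariates again, so the estimate is
consistent if *either* model is correctly specified.

## Causal structure and adjustment set

The working causal model treats the effect of employment on income as
instantaneous within a wave, and blocks confounding of the
exposure--outcome and mediator--outcome relations with:

* time-invariant confounders: gender, ethnicity (White/non-White),
  education (high/medium/low);
* time-varying confounders at $t-1$: housing tenure, benefits receipt,
  relationship status, number of children under 16, SF-12 physical
  component score (PCS), region (12 levels);
* $t-1$ values of the exposure, log equivalised income, CMD caseness,
  and the SF-12 mental component score (MCS);
* age and squared age.

Because the same intermediate confounders are identified for
employment and income, there are no exposure-induced
mediator--outcome confounders, and the CDE is identified by adding a
second, mediator-specific weight rather than by g-computation over
intermediates.

## The estimator, step by step

1. **Derivation** (`derive_caseness`, `derive_poverty`,
   `equivalise_income`, `log_income`): caseness is GHQ-12 $\ge 4$;
   relative poverty is equivalised after-housing-cost income below 60%
   of the sample median (computed once per table, unweighted -- the
   national-median alternative is not available offline, and the flag
   is recorded with its poverty line); income enters models as a
   natural log, floored at 1 GBP/month so that zero incomes stay
   finite.
2. **Lagging** (`build_analysis_table`): each outcome row pairs wave-$t$
   exposure, mediator, and outcome with wave-$(t-1)$ covariates. First
   observed waves contribute baseline information only; gaps yield no
   outcome row rather than an imputed lag.
3. **Exposure weights** (`fit_exposure_weights`): denominator
   $P(A_t \mid V, \text{age}, \text{age}^2, L_{t-1})$ by logistic
   regression; numerator the marginal $P(A_t)$. We use the marginal
   (intercept-only) numerator deliberately: a numerator conditioning on
   baseline covariates would leave those covariates imbalanced in the
   weighted pseudo-population, defeating the standardised-mean-
   difference diagnostics that are part of the analysis (all SMDs are
   expected below 0.1 after weighting, with lagged employment by far
   the most imbalanced covariate before weighting).
4. **Mediator weights** (`fit_mediator_weights`, CDE only): the ratio
   of two conditional normal densities of concurrent log income,
   numerator given exposure and baseline confounders, denominator
   additionally given age and the full lagged set; both are linear
   regressions with fitted residual standard deviations. Poverty is a
   deterministic function of income given the sample median, so it is
   not weighted separately; it enters the CDE outcome model as a
   covariate.
5. **Outcome model** (`weighted_logistic`): weighted pooled logistic
   regression of caseness on the exposure and the full adjustment set
   (CDE mode adds concurrent log income and poverty), by IRLS on the
   weight-multiplied Bernoulli likelihood; convergence at $10^{-10}$
   relative deviance change, maximum 100 iterations, with rank
   deficiency and separation reported by name.
6. **Marginal standardisation** (`marginal_standardise`): every row is
   predicted with the exposure forced on and off, other columns
   (including the mediator in CDE mode -- a "natural-value" controlled
   contrast; a fixed reference level can be obtained by setting the
   mediator column) at observed values; weight-averaged risks give the
   marginal odds ratio, the risk difference in percentage points, the
   standardised unexposed prevalence, and the population attributable
   fraction $100 \times (\text{prev}_{\text{total}} -
   \text{prev}_{\text{unexposed}})/\text{prev}_{\text{total}}$. The
   conditional (model-coefficient) odds ratio is also kept; published
   odds ratios in this literature are typically on that scale, and the
   two differ by non-collapsibility.
7. **Inference** (`run_mediation`): persons are resampled with
   replacement (all waves together); each replicate re-runs the whole
   estimator. Intervals are $\hat\theta \pm 1.96\,\widehat{se}$ (the
   bootstrap replicates are close to normal and published intervals for
   these quantities are symmetric); odds ratios use the log scale, and
   percentile intervals are kept alongside. Replicates where the
   estimator fails are dropped and counted, with a warning above 20%.

### Missing data

Observations missing more than 9 of the 22 analysis variables are
dropped (`drop_high_missingness`); the rest are completed by chained
equations (`impute_mice`): predictive mean matching with 5 donors for
continuous variables, logistic draws for binaries, multinomial draws
for categoricals, visiting variables in order of increasing
missingness, 10 iterations per chain with a mean-trace diagnostic,
gender, age, wave and number of children always among the predictors,
and rows with missing region dropped beforehand. Caseness and poverty
are dichotomised *after* imputation of the continuous GHQ and income
scores. Point estimates pool the $m = 20$ completed datasets by their
mean (odds ratios on the log scale); each bootstrap replicate resamples
the pre-imputation table and is imputed once, because nesting all $m$
imputations inside every one of $B = 1000$ replicates buys little
statistical precision for a twenty-fold computational cost.

## The synthetic panel and its oracle

`generate_panel()` simulates the study conditions end to end: nine
annual waves of adults entering at ages 25--56 (so every person-wave is
inside 25--64), a persistent binary non-employment process driven by
lagged covariates, log-normal equivalised household income responding
instantaneously to employment, and a logistic CMD process with a direct
non-employment term and a log-income term. Time-varying covariates
evolve as Markov chains that respond to *last* wave's employment --
precisely the feedback that makes naive regression adjustment
inadequate and weighting necessary. Income and CMD depend on
time-varying covariates only at $t-1$, so the estimator's lagged
adjustment set is correctly specified by construction; passing recovery
tests therefore demonstrates estimator correctness under the model's
own assumptions, not robustness to the unmeasured confounding,
attrition, survey weighting, or household clustering of real cohort
data, none of which the generator emulates.

Default parameters are calibration constants fixed once against the
emulated conditions: about 25.7% of person-wave observations not in
paid work, marginal caseness prevalence near 19%, a mean equivalised
income loss near 295 GBP/month on newly entering non-employment, a
conditional total-effect odds ratio near 1.66, and roughly 14% of the
total effect mediated by income. Region is carried as a 12-level
confounder with no structural effect. Ages advance exactly one year per
wave; real panels have variable spacing, which continuous age terms
absorb only approximately -- untested here.

`oracle_effects()` is the package's independent truth: it re-simulates
the structural equations and, at every person-wave, evaluates CMD risk
under interventions on contemporaneous non-employment with the same
income noise draw -- income responding for the TE, income held at its
employed-state draw for the CDE -- and pools over waves and persons,
reporting a person-clustered Monte-Carlo standard error. The estimator
holds the mediator at natural values instead; with the additive-logit
generator the two CDE conventions differ by far less than bootstrap
noise at the scales tested (a fraction of a percentage point on
percent mediation).

`inject_missingness()` blanks values with probabilities depending only
on gender (centred so the marginal rate hits its target): missing at
random by construction. Generated panels are complete by default;
missingness is opt-in configuration.

## Numerical choices

* Point estimation is double precision throughout; IRLS stops at
  $10^{-10}$ relative deviance change.
* The bootstrap engine re-fits four logistic and two linear models per
  replicate. Replicates enter as person-multiplicity frequency weights
  (likelihood-identical to stacking rows, with no row copies), fits are
  warm-started from the full-sample coefficients, and the IRLS runs in
  single precision in a per-model orthonormal (QR) basis -- the QR
  keeps the float normal equations well conditioned even where raw
  columns are nearly collinear, as age and squared age are inside a
  narrow age stratum. Engine replicates agree with the double-precision
  reference path to about $10^{-4}$ relative; they feed only standard
  errors.
* Weight truncation is off by default (the primary analysis is
  untruncated); `truncate_weights` clips at configurable percentiles
  (1/99 suggested for small samples) and records the clipped fraction.
* Ties in PMM donors resolve by random draw among the 5 nearest; the
  degenerate all-identical-response outcome and perfectly separated
  fits raise errors naming the culprit column.
* Seeds: one master seed drives panel generation, imputation
  (`seed + 1`), bootstrap resampling, and per-replicate imputations
  (`seed + 1000 + b`), so identical seeds reproduce reports
  byte-for-byte.

## Problem sizes used in the shipped validation

The test suite validates balance on a panel of 20,000 persons by 9
waves (every post-weighting SMD below 0.1 for both TE and CDE weights),
and interval calibration on 100 independent panels of 3,000 persons
with $B = 200$ bootstrap resamplings and $m = 5$ (coverage of the
oracle percent mediation at the 95% level, and centring of the percent
mediation on zero when the mediated pathway is switched off). These
sizes were chosen as the smallest at which the checked properties are
statistically sharp; the estimator itself has no special casing by
sample size.

## Known limitations

* The CDE is a "natural-value" controlled contrast unless a reference
  mediator level is imposed; with exposure--mediator interactions in
  the true outcome process the two conventions diverge.
* The mediator weight models log income as conditionally normal; gross
  violations (point masses, heavy tails beyond log-normality) would
  misspecify the density ratio. Whether the income pathway should be
  blocked on the continuous scale, the poverty indicator, or both is a
  substantive choice; this package blocks the continuous scale and
  records that in the manifest.
* Percent mediation is a ratio of risk differences: when the total
  effect is near zero the quantity is unstable, and replicates where it
  is undefined are dropped and counted.
* No survey design weights, household clustering, informative
  attrition, or MNAR sensitivity analyses; the bootstrap treats persons
  as independent.
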