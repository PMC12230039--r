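---
title: "Validating mortality risk scores for fragility hip fracture cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating mortality risk scores for fragility hip fracture cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragscore)
```

## The problem

Elderly patients who fracture a hip through low-energy trauma — a fragility
hip fracture, the hallmark complication of osteoporosis — face 1-year
post-operative mortality in the 15–30% range. Several bedside scoring
systems exist to quantify that risk at admission: the Sernbo score, the
Jiang et al. comorbidity model, the Nottingham Hip Fracture Score (NHFS),
the Holt et al. regression model, HEMA (Hip fracture Estimator of Mortality
Amsterdam), the ASAgeCoGeCC score and SHiPS (Shizuoka Hip fracture
Prognostic Score). None was developed on the same population, horizon, or
variable set, so before any is used to triage care it must be *externally
validated*: scored on an independent cohort and judged on discrimination
(does it rank decedents above survivors?), calibration (do predicted
probabilities match observed frequencies?) and risk stratification (do the
nominal risk groups behave as labelled?).

`fragscore` implements the seven calculators and that whole validation
pipeline, plus a seeded synthetic cohort generator so every stage can be
exercised and tested end-to-end without patient data.

## The score calculators

Every weight, cutoff and transform lives in a packaged YAML configuration
(`load_model_config()`), not in code. Two cells of the source weight table
are corrupted in print — the ASAgeCoGeCC CCI weights (the default uses 3
points for CCI 3–4 and 7 for CCI > 4, flagged unverified in the config) and
the HEMA low-risk predicted mortality (the default uses the 5.6% stated in
the accompanying text) — and a config file can be corrected against the
original publications without touching the package.

Points of note per model:

* **Sernbo** (age, habitat, walking aids, mental status; each 2 or 5
  points) is inverted relative to the others: higher totals mean *better*
  survival. The configuration records this as an `orientation` flag; the
  validation layer reports the AUC both on the score as published and
  orientation-corrected. The source text lists attainable totals
  "8, 11, 13, 17, 20", but four items of {2, 5} cannot sum to 13 —
  brute-force enumeration (`enumerate_scores("sernbo")`) gives
  {8, 11, 14, 17, 20}, and 14 is the moderate-risk cutoff used.
* **NHFS** publishes a logistic transform for 30-day mortality,
  `100/(1 + exp(5.0122 − 0.481 S))`; `nhfs_probability()` evaluates it.
  Because the validation setting is retrospective, a recorded history of
  cognitive impairment stands in for the Abbreviated Mental Test Score;
  reports carry that adaptation in their metadata.
* **Holt** sums published regression coefficients (including a negative
  female coefficient — the one deliberate exception to "adverse findings
  never lower a score"). Its logistic intercept was never published, so
  `holt_probability()` refuses to run unconfigured;
  `holt_intercept_from_bounds()` derives −4.79 by inverting the published
  high-risk stratum bounds (score 2 ↔ 5.8%, score 4.92 ↔ 53.2%), and
  reproduces both to one decimal.
* **SHiPS** prints a maximum total of 64, but the printed weights sum to at
  most 60 (enumeration again); the strata keep the printed 25–64 band. The
  model has no weight for pathological fractures, so scoring one is a
  per-patient error — such fractures are excluded by the eligibility filter
  anyway.
* Decimal-weighted models (Holt, HEMA) accumulate in integer hundredths,
  so stratum-boundary comparisons are exact rather than float-dependent.

Missing required variables raise per-patient errors naming the variable;
per-variable defaults are available but strictly opt-in, because silent
imputation would corrupt a validation study.

## Validation statistics

All discrimination and calibration statistics are implemented in the
package (the `pROC` package is used only as an independent cross-check in
the test suite):

* **AUC** is the Mann–Whitney rank statistic with ties counting one half;
  its confidence interval uses the DeLong placement-value variance.
  `delong_test()` compares two correlated AUCs on the same patients.
* **Hosmer–Lemeshow** bins patients by quantiles of predicted risk. Stratum
  -level probability sources produce heavy ties, so when there are no more
  distinct predicted values than requested groups, each distinct value
  forms its own bin; bins with zero expected deaths or survivors are merged
  into a neighbour. Because the predictions under validation are *fixed*
  (nothing is refit on the cohort), the statistic is referred to chi-square
  with *g* degrees of freedom — under simulation from the true
  probabilities this holds the nominal 5% type-I error, whereas the
  development-data convention *g* − 2 rejects at roughly twice the nominal
  rate in the same simulation. `fit_adjusted = TRUE` restores *g* − 2 for
  predictions fit in-sample.
* **Calibration slope/intercept** regresses the outcome on the logit of the
  prediction via a Newton–Raphson fit written here (tolerance 1e-8, 50
  iterations, predictions clipped to [1e-6, 1 − 1e-6]); constant
  predictions, separation or non-convergence yield a flagged result rather
  than an error.
* **Confusion metrics** default to the Youden-optimal threshold (the
  source study never states its threshold rule); ties break toward higher
  specificity. The threshold is recorded in every report.
* **Stratum accuracy** quantifies predicted-versus-observed agreement per
  risk group as `100 × min(p, o) / max(p, o)` — symmetric, 100 iff the two
  agree, 0 when one is zero. Interval-valued nominal mortalities (e.g.
  NHFS high risk, 10.7–33.6%) are collapsed to a representative value —
  the upper bound by default, configurable, since published tables are
  not consistent about which bound they use.
* **`hanley_mcneil_n()`** inverts the Hanley–McNeil AUC standard error to a
  minimum cohort size. Note the variance components for cases and controls
  are asymmetric, so the minimizing prevalence is slightly above one half
  (≈0.6 at AUC 0.7), not exactly balanced.

### Probability sources for calibration

Only NHFS publishes a usable per-patient probability transform (Holt does
once an intercept is configured). For Jiang, HEMA, ASAgeCoGeCC and SHiPS
the default calibration input is the piecewise-constant stratum-level
nominal mortality from the configuration. Sernbo publishes no probabilities
at all, and Holt ships with no intercept, so their default source is
in-sample logistic recalibration of the raw score — which makes their
calibration slope 1 *by construction*; every report labels its probability
source so this tautology is visible. This is the honest menu available
from the published material; it is also why stratum-level sources yield
few Hosmer–Lemeshow bins.

## The synthetic cohort generator

`generate_cohort()` emulates the marginal structure of the reference
population: median age 83 with quartiles 71/95 (a shifted beta on
[60, 100] fit to those quantiles; because an IQR that wide is unusual, an
alternative `age_preset = "range"` reads 71–95 as the observed range),
77.8% female, 97.1% with ≥2 comorbidities, 46.9% ASA > 2, 2.4% cognitive
impairment, 7.2% institutional residence, 23.2% dependent mobility, and a
29.0% expected 1-year mortality. Comorbidity-flag prevalences that the
reference publishes only as model inputs (COPD, CHF, renal disease, …) are
set to values typical of geriatric hip-fracture series and are individually
configurable.

Dependence is induced by a single latent frailty: a standard-normal
variable loaded on age (loading 0.6) that raises every adverse covariate's
probability (logit loading 0.8 per SD), rather than a full copula — the
minimal mechanism that makes every score discriminate and populates the
high-risk strata. Each covariate's intercept is solved so its *expected*
prevalence on the realised frailty sample equals the target; realised
prevalences remain binomially variable.

Death risk follows a logistic model on standardised age, frailty, male sex,
ASA grade, CCI and dependent mobility (coefficients 0.9, 0.9, 0.5, 0.5,
0.3, 0.4 per SD — moderate, epidemiologically plausible effects), with the
intercept solved so the mean simulated risk equals the target mortality.
Event times are Weibull with shape 0.8 (hazard concentrated early, matching
the observed excess first-year risk), anchored so that the probability of
death within 12 months equals the modelled risk; censoring is
administrative, uniform between 12 and 62 months (uniform accrual against a
fixed study end, so every patient has at least a year of potential
follow-up and the binary endpoint — death within 12.0 months, boundary
inclusive — is always observed).

What passing tests on this cohort do **not** show: the generator matches
stated marginals plus one-factor dependence only. Real cohorts have richer
covariance (e.g. sex-specific age structure, clustered comorbidities),
measurement error in ASA grading and comorbidity coding, and non-
administrative loss to follow-up. Agreement of the pipeline on synthetic
data validates the *machinery*, not any claim about how the seven models
rank on a real population.

## Numerical and design choices

* Strata are validated at load time: ordered, disjoint (open/closed bounds
  explicit — Holt's `<1` and `>2` cutoffs are open), and covering the
  brute-force-enumerated attainable score set.
* Stratum assignment compares at 1e-9 tolerance against exact-hundredth
  scores, so boundary cases (HEMA 2.5, Holt 2.0) are deterministic.
* The DeLong comparison returns z = 0, p = 1 when the variance of the AUC
  difference is exactly zero (identical scores).
* Pipeline outputs contain no timestamps; a rerun with the same
  configuration is byte-identical.
* Raw pairwise DeLong p-values are reported without multiplicity
  adjustment, matching common practice in validation studies; adjust
  downstream if desired.

Simulation sizes used by the test suite were chosen to give tight
Monte-Carlo error at interactive runtimes: 500 replicates at n = 2000 for
the Hosmer–Lemeshow type-I property, 200 replicates at n = 5000 for
calibration-slope CI coverage, 500 replicates at 500 per arm for the
log-rank null, 4000 paired-bootstrap replicates for the DeLong oracle
(Monte-Carlo SE ≈ 0.004 on the compared p-value), and n = 2000 cohorts for
the qualitative discrimination pattern.

## Worked example

```{r, eval = FALSE}
library(fragscore)

bundle <- run_pipeline(run_config(sim = cohort_sim_config(n = 207, seed = 1),
                                  out_dir = "report"))
writeLines(render_table3(bundle$reports))
writeLines(render_table4(bundle$reports))
```

## Known limitations

* Holt and Sernbo calibration is only assessable after recalibration (see
  above), so their slope/H-L entries describe the recalibrated score, not
  the published model.
* HEMA's published 30-day probability formula is referenced but not
  printed in the source material; its calibration uses stratum-level
  values.
* The CCI is an input field; the package does not compute it from
  diagnoses.
* No Cox modelling or time-dependent AUC: the validation endpoint is
  binary 1-year status, with Kaplan–Meier/log-rank machinery for the
  survival descriptives only.
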