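# fragscore

Seven published mortality risk scores for elderly fragility hip fracture
patients — Sernbo, Jiang et al., the Nottingham Hip Fracture Score (NHFS),
Holt et al., HEMA, ASAgeCoGeCC and SHiPS — together with the full
external-validation toolkit used to compare them on a cohort, and a seeded
synthetic cohort generator so the pipeline runs end-to-end without patient
data.

## Who this is for

Clinical researchers validating hip-fracture prognostic models on a local
cohort, and methodologists who need the underlying statistics as plain,
testable functions:

* **Calculators** — `score_nhfs()`, `score_ships()`, … and `score_all()`.
  Every weight table, probability transform and risk-stratum cutoff lives
  in an editable YAML configuration (`load_model_config()`), with
  attainable-score enumeration (`enumerate_scores()`) validating that the
  strata cover each model's score range.
* **Discrimination** — `roc_auc()` (Mann–Whitney AUC, ties half-weighted,
  DeLong confidence interval) and `delong_test()` (paired comparison of
  correlated AUCs via placement-value covariance).
* **Calibration** — `hosmer_lemeshow()` (quantile bins with
  tie-consolidation) and `calibration_slope()` (Newton–Raphson logistic
  regression of outcome on logit(prediction); slope 1 = ideal).
* **Classification** — `confusion_metrics()` at an explicit or
  Youden-optimal threshold (sensitivity, specificity, PPV, NPV).
* **Risk stratification** — `stratum_table()` and the symmetric agreement
  statistic `stratum_accuracy(p, o) = 100·min(p,o)/max(p,o)`.
* **Survival** — `km_estimate()` / `logrank_test()` (product-limit curve,
  two-group comparison), and `hanley_mcneil_n()` for AUC-precision sample
  sizes.
* **Cohorts** — `read_cohort()` / `write_cohort()` with a remappable CSV
  schema, `filter_eligible()` implementing the fragility-fracture
  eligibility rules (age ≥ 60, DXA T ≤ −2.5, surgical, first admission per
  patient, drop lost-to-follow-up), and `generate_cohort()` for seeded
  synthetic cohorts.

Key published quantities are reproduced exactly: the NHFS transform
`100/(1 + exp(5.0122 − 0.481·S))` gives 4.4% / 6.9% / 10.7% / 33.6% at
scores 4/5/6/9, and `holt_intercept_from_bounds()` recovers the unpublished
Holt intercept (−4.79) from the published stratum bounds.

## Worked example

Score one patient:

```r
library(fragscore)
score_nhfs(data.frame(patient_id = "pt01", age = 83, sex = "female",
                      hemoglobin = 11, cognitive_impairment = FALSE,
                      residence = "own_home", n_comorbidities = 3,
                      malignancy = "none"))
#>   patient_id model raw_score predicted_prob      stratum
#> 1       pt01  nhfs         4     0.04359663 intermediate
```

Age 83 contributes 3 points and ≥2 comorbidities 1 point; an NHFS of 4 maps
to a predicted 30-day mortality of 4.4% and the intermediate-risk stratum.

Run the whole validation pipeline on a simulated 207-patient cohort:

```r
bundle <- run_pipeline(run_config(sim = cohort_sim_config(n = 207, seed = 1),
                                  out_dir = "report"))
writeLines(render_table3(bundle$reports))
#> model              auc_95ci          hl_p  calibration_slope_95ci  sensitivity  specificity  ppv   npv
#> Sernbo score       0.25 (0.18-0.31)  0.13  1.00 (0.64, 1.36)       0.94         0.43         0.44  0.94
#> Jiang et al.       0.74 (0.67-0.81)  0.08  1.67 (1.00, 2.34)       0.55         0.84         0.63  0.80
#> NHFS               0.75 (0.69-0.81)  0.00  2.01 (1.26, 2.75)       0.87         0.49         0.45  0.88
#> Holt et al.        0.79 (0.73-0.86)  0.94  1.00 (0.68, 1.32)       0.81         0.64         0.52  0.87
#> HEMA               0.67 (0.59-0.75)  0.00  0.19 (0.09, 0.29)       0.79         0.46         0.41  0.82
#> ASAgeCoGeCC score  0.78 (0.72-0.85)  0.00  0.49 (0.30, 0.69)       0.73         0.68         0.52  0.84
#> SHiPS              0.79 (0.72-0.85)  0.00  1.26 (0.87, 1.66)       0.75         0.70         0.54  0.85
```

Reading the table: on this synthetic cohort every model except Sernbo
discriminates (AUC ≳ 0.7); Sernbo's 0.25 reflects its inverted orientation
(higher score = better survival — the report also carries the
orientation-corrected AUC, 0.75). Low Hosmer–Lemeshow p-values flag the
30-day probability transforms and stratum-level nominal mortalities as
miscalibrated against a 1-year endpoint; the Sernbo and Holt slopes of 1.00
are by construction, because those models publish no usable probabilities
and are recalibrated in-sample (each report labels its probability source).
`render_table4(bundle$reports)` gives the per-stratum
predicted-versus-observed table, with empty strata shown as `None`, and the
output directory receives panels CSV, per-model report JSON, the pairwise
DeLong matrix, both rendered tables, the Kaplan–Meier curve TSV and a run
manifest. Reruns with the same configuration are byte-identical.

See the vignette (`vignettes/validating-hip-fracture-risk-scores.Rmd`) for
the models, statistics, generator design and their assumptions.

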