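# Fixture builders: a healthy-baseline patient record with field overrides,
# and small cohorts assembled from it. All fixtures are built in code.

make_patient <- function(..., patient_id = "P1") {
  base <- list(
    patient_id = patient_id, age = 70L, sex = "female",
    residence = "own_home", mobility = "no_aids", mental_status = "alert",
    cognitive_impairment = FALSE, asa_grade = 2L, hemoglobin = 12,
    serum_urea = 5, cci = 0L, n_comorbidities = 0L,
    fracture_type = "femoral_neck", in_hospital_fracture = FALSE,
    nursing_care_certification = FALSE, copd = FALSE, pneumonia = FALSE,
    ischemic_heart_disease = FALSE, prior_mi = FALSE, arrhythmia = FALSE,
    chf = FALSE, malnutrition = FALSE, electrolyte_disorder = FALSE,
    renal_disease = FALSE, liver_disease_moderate_severe = FALSE,
    deficiency_anemia = FALSE, chronic_pulmonary_disease = FALSE,
    malignancy = "none", dxa_t_score = -3.0, treated_surgically = TRUE,
    periprosthetic = FALSE, admission_date = "2020-01-15",
    dead_1y = FALSE, followup_months = 24, lost_to_followup = FALSE)
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_patients <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) {
    if (!"patient_id" %in% names(rows[[i]]) ||
        all(rows[[i]]$patient_id == "P1")) {
      rows[[i]]$patient_id <- paste0("P", i)
    }
  }
  do.call(rbind, rows)
}

# exhaustive concordant-pair AUC oracle (ties count one half)
auc_pair_oracle <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# hand product-limit survival oracle at the event times
km_product_oracle <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}
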