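{
  "description": "Default column mapping and categorical encodings for cohort CSV files. 'columns' maps canonical field names to CSV header names; 'levels' maps raw CSV values to canonical levels for each categorical field. Copy and edit to adapt to a local export format.",
  "columns": {
    "patient_id": "patient_id",
    "age": "age",
    "sex": "sex",
    "residence": "residence",
    "mobility": "mobility",
    "mental_status": "mental_status",
    "cognitive_impairment": "cognitive_impairment",
    "asa_grade": "asa_grade",
    "hemoglobin": "hemoglobin",
    "serum_urea": "serum_urea",
    "cci": "cci",
    "n_comorbidities": "n_comorbidities",
    "fracture_type": "fracture_type",
    "in_hospital_fracture": "in_hospital_fracture",
    "nursing_care_certification": "nursing_care_certification",
    "copd": "copd",
    "pneumonia": "pneumonia",
    "ischemic_heart_disease": "ischemic_heart_disease",
    "prior_mi": "prior_mi",
    "arrhythmia": "arrhythmia",
    "chf": "chf",
    "malnutrition": "malnutrition",
    "electrolyte_disorder": "electrolyte_disorder",
    "renal_disease": "renal_disease",
    "liver_disease_moderate_severe": "liver_disease_moderate_severe",
    "deficiency_anemia": "deficiency_anemia",
    "chronic_pulmonary_disease": "chronic_pulmonary_disease",
    "malignancy": "malignancy",
    "dxa_t_score": "dxa_t_score",
    "treated_surgically": "treated_surgically",
    "periprosthetic": "periprosthetic",
    "admission_date": "admission_date",
    "dead_1y": "dead_1y",
    "followup_months": "followup_months",
    "lost_to_followup": "lost_to_followup"
  },
  "levels": {
    "sex": {
      "male": "male", "female": "female",
      "M": "male", "F": "female"
    },
    "residence": {
      "own_home": "own_home",
      "sheltered_or_assisted": "sheltered_or_assisted",
      "long_term_care": "long_term_care",
      "rehabilitation": "rehabilitation",
      "acute_ward": "acute_ward"
    },
    "mobility": {
      "no_aids": "no_aids",
      "one_aid": "one_aid",
      "two_aids_or_frame": "two_aids_or_frame",
      "requires_accompaniment": "requires_accompaniment",
      "unable_to_walk": "unable_to_walk"
    },
    "mental_status": {
      "alert": "alert",
      "slight_confusion": "slight_confusion"
    },
    "fracture_type": {
      "femoral_neck": "femoral_neck",
      "intracapsular": "femoral_neck",
      "pertrochanteric": "pertrochanteric",
      "extracapsular": "pertrochanteric",
      "subtrochanteric": "subtrochanteric",
      "pathological": "pathological"
    },
    "malignancy": {
      "none": "none", "skin": "skin", "other": "other",
      "metastatic": "metastatic"
    }
  }
}
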