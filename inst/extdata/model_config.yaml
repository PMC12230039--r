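# Default weight tables, probability transforms and risk-stratum cutoffs for
# the seven fragility hip fracture mortality scores.  Editable without code
# changes: two cells of the source weight table are known to be corrupted in
# print (see the asagecogecc `cci` note and the hema low-risk predicted value)
# and can be corrected here against the original model publications.
#
# Conventions
#   orientation: ascending  -> higher score = higher predicted mortality
#                descending -> higher score = better survival (Sernbo)
#   strata: ordered, disjoint, covering each model's attainable score range;
#           min/max are inclusive; predicted is the nominal short-term
#           mortality in percent (scalar, [lo, hi] interval, or null when the
#           source publishes none).
#   probability_source: how per-patient predicted probabilities are obtained
#           for calibration analyses: "formula" (published logistic
#           transform), "strata" (piecewise-constant stratum values), or
#           "recalibrate" (in-sample logistic recalibration of the raw score,
#           used where the source publishes no usable probabilities).
version: 1
models:
  sernbo:
    label: "Sernbo score"
    orientation: descending
    probability_source: recalibrate
    variables:
      age:                    # years at admission
        breaks: [80]          # <80 | >=80
        weights: [5, 2]
      residence:              # "habitat"
        own_home: 5
        sheltered_or_assisted: 2
        long_term_care: 2
        rehabilitation: 2
        acute_ward: 2
      mobility:               # walking aids: none or one stick vs worse
        no_aids: 5
        one_aid: 5
        two_aids_or_frame: 2
        requires_accompaniment: 2
        unable_to_walk: 2
      mental_status:
        alert: 5
        slight_confusion: 2
    strata:                   # higher total = better survival
      - {label: high,         min: 8,  max: 11, predicted: null}
      - {label: intermediate, min: 14, max: 14, predicted: null}
      - {label: low,          min: 17, max: 20, predicted: null}
  jiang:
    label: "Jiang et al."
    orientation: ascending
    probability_source: strata
    variables:
      age:
        breaks: [70, 80, 90]  # 60-69 | 70-79 | 80-89 | >=90
        weights: [0, 6, 7, 13]
      sex: {male: 6, female: 0}
      residence_long_term_care: 4
      copd: 4
      pneumonia: 14
      ischemic_heart_disease: 5
      prior_mi: 13
      arrhythmia: 5
      chf: 7
      malignancy_any: 13
      malnutrition: 20
      electrolyte_disorder: 5
      renal_disease: 19
    strata:
      - {label: low,          min: 0,  max: 7,   predicted: 12.1}
      - {label: intermediate, min: 8,  max: 21,  predicted: [22.9, 36.5]}
      - {label: high,         min: 22, max: 145, predicted: 52.0}
  nhfs:
    label: "NHFS"
    orientation: ascending
    probability_source: formula
    transform: {type: logistic_pct, intercept: 5.0122, slope: 0.481}
    variables:
      age:
        breaks: [66, 86]      # <66 | 66-85 | >=86
        weights: [0, 3, 4]
      sex: {male: 1, female: 0}
      hemoglobin_le_10: 1     # admission Hb <= 10 g/dL
      cognitive_impairment: 1 # history of cognitive impairment in place of AMTS
      institutional_residence: 1
      two_or_more_comorbidities: 1
      malignancy_any: 1
    strata:
      - {label: low,          min: 0, max: 3,  predicted: 2.7}
      - {label: intermediate, min: 4, max: 5,  predicted: [4.4, 6.9]}
      - {label: high,         min: 6, max: 10, predicted: [10.7, 33.6]}
    notes: >
      The cognitive item substitutes a recorded history of cognitive
      impairment for the Abbreviated Mental Test Score; reports carry this
      adaptation in their metadata.
  holt:
    label: "Holt et al."
    orientation: ascending
    probability_source: recalibrate  # switches to the formula when an intercept is set
    transform: {type: logistic, intercept: null}  # 30-day intercept not published;
                                                  # see holt_intercept_from_bounds()
    variables:
      age:
        breaks: [60, 70, 80, 90]
        weights: [0, 0.58, 1.24, 1.74, 1.96]
      asa_grade:
        breaks: [3, 4]        # 1-2 | 3 | 4-5
        weights: [0, 0.80, 1.62]
      sex: {male: 0, female: -0.65}
      residence:
        own_home: 0
        sheltered_or_assisted: 0   # not a level of the source model; grouped with own home
        long_term_care: 0.53
        rehabilitation: 0.53
        acute_ward: 0.59
      mobility:
        no_aids: 0
        one_aid: -0.02
        two_aids_or_frame: 0.07
        requires_accompaniment: 0.24
        unable_to_walk: 0.45
      fracture_type:
        femoral_neck: 0       # intracapsular
        pertrochanteric: 0.12 # extracapsular
        subtrochanteric: 0.28
        pathological: 1.32
    strata:
      - {label: low,          min: -0.67, max: 1,    predicted: [0, 2.2],
         open_max: true}      # score < 1
      - {label: intermediate, min: 1,     max: 2,    predicted: [2.2, 5.8]}
      - {label: high,         min: 2,     max: 5.94, predicted: [5.8, 53.2],
         open_min: true}      # score > 2
  hema:
    label: "HEMA"
    orientation: ascending
    probability_source: strata
    variables:
      age:
        breaks: [85]          # >=85 scores 1
        weights: [0, 1]
      in_hospital_fracture: 2
      malnutrition: 2
      prior_mi: 1
      chf: 1
      pneumonia: 2
      renal_disease: 1
      malignancy_any: 1.5
      serum_urea_gt_9: 0.5
    strata:
      # low-risk predicted prints corrupted ("<=E.6"); 5.6 from the source's
      # stated low-risk estimated mortality.
      - {label: low,          min: 0,   max: 1,  predicted: 5.6}
      - {label: intermediate, min: 1.5, max: 2,  predicted: [8.9, 13.9]}
      - {label: high,         min: 2.5, max: 12, predicted: [21.0, 99.1]}
  asagecogecc:
    label: "ASAgeCoGeCC score"
    orientation: ascending
    probability_source: strata
    variables:
      age:
        breaks: [75, 86]      # <75 | 75-85 | >85
        weights: [0, 1, 2]
      cci:                    # age-adjusted Charlson Comorbidity Index
        # Source table cell corrupted ("3-4 | 3-37"); 3 points for CCI 3-4 and
        # 7 for CCI >4 adopted as the default, unverified against the original
        # publication.  Correct here if needed.
        breaks: [3, 5]        # <3 | 3-4 | >4
        weights: [0, 3, 7]
      cognitive_impairment: 1
      asa_grade:
        breaks: [3, 4]        # <3 | 3 | >3
        weights: [0, 1, 2]
      sex: {male: 1, female: 0}
    strata:
      - {label: low,          min: 0, max: 6,  predicted: 1.1}
      - {label: intermediate, min: 7, max: 8,  predicted: 18.0}
      - {label: high,         min: 9, max: 13, predicted: 50.4}
  ships:
    label: "SHiPS"
    orientation: ascending
    probability_source: strata
    variables:
      sex: {male: 8, female: 0}
      age:
        breaks: [75, 85, 95]  # 65-74 | 75-84 | 85-94 | >=95
        weights: [0, 5, 10, 16]
      fracture_type:
        femoral_neck: 1
        pertrochanteric: 1
        subtrochanteric: 0
        # pathological: no published weight; scoring it is a per-patient error
      nursing_care_certification: 8
      malignancy:             # mutually exclusive categories
        none: 0
        skin: 0
        other: 3
        metastatic: 9
      liver_disease_moderate_severe: 8
      renal_disease: 4
      chf: 3
      deficiency_anemia: 2
      chronic_pulmonary_disease: 1
    strata:
      # printed total range is 0-64 although the printed weights sum to 60
      - {label: low,          min: 0,  max: 9,  predicted: 3.0}
      - {label: intermediate, min: 10, max: 17, predicted: 9.0}
      - {label: high,         min: 18, max: 24, predicted: 16.0}
      - {label: very_high,    min: 25, max: 64, predicted: 31.0}
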