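# Hand-scored fixture patients per model, attainable-score enumeration, and
# orientation/monotonicity properties.

expect_score <- function(panel, score, stratum) {
  expect_equal(panel$raw_score, score)
  expect_equal(panel$stratum, stratum)
}

test_that("Sernbo hand-scored fixtures match", {
  expect_score(score_sernbo(make_patient(age = 70L)), 20, "low")
  expect_score(score_sernbo(make_patient(
    age = 85L, residence = "sheltered_or_assisted",
    mobility = "two_aids_or_frame", mental_status = "slight_confusion")),
    8, "high")
  expect_score(score_sernbo(make_patient(
    age = 85L, mobility = "one_aid", mental_status = "slight_confusion")),
    14, "intermediate")  # 2 + 5 + 5 + 2
})

test_that("Jiang hand-scored fixtures match", {
  expect_score(score_jiang(make_patient(
    age = 92L, sex = "male", malnutrition = TRUE, renal_disease = TRUE)),
    13 + 6 + 20 + 19, "high")
  expect_score(score_jiang(make_patient(age = 65L)), 0, "low")
  expect_score(score_jiang(make_patient(
    age = 75L, residence = "long_term_care", pneumonia = TRUE)),
    6 + 4 + 14, "high")
})

test_that("NHFS hand-scored fixtures match", {
  expect_score(score_nhfs(make_patient(
    age = 83L, hemoglobin = 11, n_comorbidities = 3L)),
    4, "intermediate")  # age 3 + comorbidities 1
  expect_score(score_nhfs(make_patient(age = 60L)), 0, "low")
  expect_score(score_nhfs(make_patient(
    age = 90L, sex = "male", hemoglobin = 9.5, cognitive_impairment = TRUE,
    residence = "long_term_care", n_comorbidities = 2L,
    malignancy = "other")),
    10, "high")  # maximum attainable
})

test_that("NHFS probability transform matches its published values", {
  expect_equal(round(nhfs_probability(4), 1), 4.4)
  expect_equal(round(nhfs_probability(9), 1), 33.6)
  expect_equal(nhfs_probability(0), 100 / (1 + exp(5.0122)), tolerance = 1e-12)
  expect_true(all(diff(nhfs_probability(0:10)) > 0))
  expect_error(nhfs_probability(11), "range")
  expect_error(nhfs_probability(-1), "range")
})

test_that("Holt hand-scored fixtures match", {
  expect_score(score_holt(make_patient(age = 83L, asa_grade = 3L)),
               1.89, "intermediate")  # 1.74 + 0.80 - 0.65
  expect_score(score_holt(make_patient(
    age = 59L, asa_grade = 1L, sex = "male")), 0, "low")
  expect_score(score_holt(make_patient(
    age = 95L, asa_grade = 4L, sex = "male", residence = "acute_ward",
    mobility = "unable_to_walk", fracture_type = "pathological")),
    5.94, "high")  # maximum attainable
})

test_that("Holt probability transform requires an intercept and inverts the published bounds", {
  expect_equal(holt_probability(0, intercept = 0), 0.5)
  expect_error(holt_probability(2), "unconfigured transform")
  ic <- holt_intercept_from_bounds()
  expect_equal(ic, -4.79)
  expect_equal(round(100 * holt_probability(2, ic), 1), 5.8)
  expect_equal(round(100 * holt_probability(4.92, ic), 1), 53.2)
  expect_true(holt_probability(2.5, ic) > holt_probability(2.0, ic))
  expect_true(holt_probability(2.5, 1) > holt_probability(2.0, 1))
})

test_that("HEMA hand-scored fixtures match", {
  expect_score(score_hema(make_patient(age = 86L, chf = TRUE,
                                       serum_urea = 10)),
               2.5, "high")  # 1 + 1 + 0.5
  expect_score(score_hema(make_patient()), 0, "low")
  all_nine <- make_patient(age = 86L, in_hospital_fracture = TRUE,
                           malnutrition = TRUE, prior_mi = TRUE, chf = TRUE,
                           pneumonia = TRUE, renal_disease = TRUE,
                           malignancy = "other", serum_urea = 10)
  expect_score(score_hema(all_nine), 12, "high")  # sum of all weights
})

test_that("ASAgeCoGeCC hand-scored fixtures match", {
  expect_score(score_asagecogecc(make_patient(cci = 2L)), 0, "low")
  # age > 85 contributes 2, male 1
  expect_score(score_asagecogecc(make_patient(age = 88L, sex = "male",
                                              asa_grade = 1L)), 3, "low")
  expect_score(score_asagecogecc(make_patient(
    age = 88L, sex = "male", cci = 6L, asa_grade = 4L,
    cognitive_impairment = TRUE)),
    2 + 7 + 1 + 2 + 1, "high")
})

test_that("SHiPS hand-scored fixtures match", {
  expect_score(score_ships(make_patient(
    age = 87L, nursing_care_certification = TRUE, renal_disease = TRUE)),
    10 + 1 + 8 + 4, "high")
  expect_score(score_ships(make_patient(
    fracture_type = "subtrochanteric")), 0, "low")
  expect_score(score_ships(make_patient(
    age = 96L, sex = "male", nursing_care_certification = TRUE,
    malignancy = "metastatic", liver_disease_moderate_severe = TRUE,
    renal_disease = TRUE, chf = TRUE, deficiency_anemia = TRUE,
    chronic_pulmonary_disease = TRUE)),
    60, "very_high")  # brute-force maximum
  expect_error(score_ships(make_patient(fracture_type = "pathological")),
               "no weight")
})

test_that("attainable score sets are fully covered by the strata", {
  expect_equal(enumerate_scores("sernbo"), c(8, 11, 14, 17, 20))
  expect_equal(max(enumerate_scores("ships")), 60)
  expect_equal(max(enumerate_scores("nhfs")), 10)
  expect_equal(range(enumerate_scores("holt")), c(-0.67, 5.94))
  cfg <- load_model_config()
  for (m in names(cfg)) {
    labels <- stratify_score(enumerate_scores(cfg[[m]]), cfg[[m]])
    expect_false(anyNA(labels), info = m)
  }
})

test_that("each stratum occupies one contiguous block of the score range", {
  cfg <- load_model_config()
  for (m in names(cfg)) {
    labels <- stratify_score(sort(enumerate_scores(cfg[[m]])), cfg[[m]])
    expect_equal(anyDuplicated(rle(labels)$values), 0L, info = m)
  }
})

test_that("adverse findings move every score in the risk direction", {
  base <- make_patient(age = 70L, asa_grade = 2L)
  worse <- list(
    list(age = 90L), list(mobility = "unable_to_walk"),
    list(mental_status = "slight_confusion"),
    list(residence = "long_term_care"), list(asa_grade = 5L),
    list(cognitive_impairment = TRUE), list(hemoglobin = 9),
    list(n_comorbidities = 4L), list(cci = 6L), list(chf = TRUE),
    list(pneumonia = TRUE), list(renal_disease = TRUE),
    list(malnutrition = TRUE), list(malignancy = "metastatic"),
    list(serum_urea = 12), list(nursing_care_certification = TRUE),
    list(deficiency_anemia = TRUE), list(chronic_pulmonary_disease = TRUE))
  cfg <- load_model_config()
  for (m in names(cfg)) {
    score_fn <- get(paste0("score_", m))
    s0 <- score_fn(base)$raw_score
    for (w in worse) {
      p <- do.call(make_patient, c(list(age = 70L, asa_grade = 2L), w))
      s1 <- score_fn(p)$raw_score
      if (cfg[[m]]$orientation == "descending") {
        expect_lte(s1, s0)
      } else {
        expect_gte(s1, s0)
      }
    }
  }
  # the two deliberate exceptions to "adverse never decreases":
  expect_lt(score_holt(make_patient(sex = "female"))$raw_score,
            score_holt(make_patient(sex = "male"))$raw_score)
  expect_lt(score_sernbo(make_patient(age = 85L))$raw_score,
            score_sernbo(make_patient(age = 70L))$raw_score)
})

test_that("missing required variables raise named scoring errors; defaults are opt-in", {
  p <- make_patient()
  p$hemoglobin <- NA_real_
  expect_error(score_nhfs(p), "missing 'hemoglobin'.*P1")
  expect_equal(score_nhfs(p, defaults = list(hemoglobin = 12))$raw_score, 3)
  p2 <- make_patient()
  p2$mobility <- NULL
  expect_error(score_sernbo(p2), "'mobility' absent")
})

test_that("score_all reports per-model failures without aborting the rest", {
  p <- make_patient()
  p$hemoglobin <- NA_real_
  panels <- score_all(p)
  expect_setdiff <- setdiff(c("sernbo", "jiang", "holt", "hema",
                              "asagecogecc", "ships"),
                            unique(panels$model))
  expect_length(expect_setdiff, 0)
  expect_named(attr(panels, "failures"), "nhfs")
  expect_match(attr(panels, "failures")$nhfs, "hemoglobin")
  expect_error(score_all(p, models = "bogus"), "unknown model")
})

test_that("config validation rejects overlapping or gapped strata", {
  cfg <- yaml::read_yaml(system.file("extdata", "model_config.yaml",
                                     package = "fragscore"))
  bad <- cfg
  bad$models$nhfs$strata[[2]]$min <- 3   # overlaps low (max 3)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, path)
  expect_error(load_model_config(path), "overlapping")

  bad <- cfg
  bad$models$nhfs$strata[[2]]$min <- 5   # leaves score 4 uncovered
  yaml::write_yaml(bad, path)
  expect_error(load_model_config(path), "do not cover")
})

test_that("per-patient predicted probabilities appear only for published transforms", {
  p <- make_patient(age = 83L)
  expect_equal(score_nhfs(p)$predicted_prob,
               nhfs_probability(score_nhfs(p)$raw_score) / 100)
  expect_true(is.na(score_holt(p)$predicted_prob))   # intercept unset
  expect_true(is.na(score_sernbo(p)$predicted_prob))
  expect_true(is.na(score_ships(p)$predicted_prob))
})
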