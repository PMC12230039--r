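# The seven risk-score calculators. Each calculator is vectorised over a
# patient data frame; weights come from the model configuration, never from
# code. Decimal-weighted models (Holt, HEMA) accumulate in integer hundredths
# so stratum-boundary comparisons are exact.

# ---- shared machinery -------------------------------------------------------

# resolve one required variable, applying opt-in defaults, erroring per
# patient otherwise (silent imputation would corrupt validation)
require_var <- function(df, var, model, defaults = list()) {
  if (!var %in% names(df)) {
    stop("scoring error (", model, "): variable '", var, "' absent",
         call. = FALSE)
  }
  x <- df[[var]]
  if (var %in% names(defaults)) x[is.na(x)] <- defaults[[var]]
  if (anyNA(x)) {
    ids <- if ("patient_id" %in% names(df)) df$patient_id[is.na(x)] else
      which(is.na(x))
    stop("scoring error (", model, "): missing '", var, "' for patient(s) ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  x
}

band_cents <- function(x, v) {
  w <- as.integer(round(100 * as.numeric(v$weights)))
  w[findInterval(x, as.numeric(v$breaks)) + 1L]
}

map_cents <- function(x, map, model, var) {
  bad <- which(!x %in% names(map))
  if (length(bad)) {
    stop("scoring error (", model, "): value '", x[bad[1]],
         "' of '", var, "' has no weight in the model", call. = FALSE)
  }
  as.integer(round(100 * as.numeric(unlist(map))))[match(x, names(map))]
}

flag_cents <- function(x, weight) {
  as.integer(round(100 * weight)) * as.integer(as.logical(x))
}

as_records <- function(p) {
  if (inherits(p, "cohort")) return(p$records)
  if (is.data.frame(p)) return(p)
  as.data.frame(p, stringsAsFactors = FALSE)
}

panel_df <- function(df, model, score, prob, spec) {
  data.frame(patient_id = if ("patient_id" %in% names(df)) df$patient_id else
               as.character(seq_len(nrow(df))),
             model = model,
             raw_score = score,
             predicted_prob = prob,
             stratum = stratify_score(score, spec),
             stringsAsFactors = FALSE)
}

# ---- raw score engines (vectorised, return score in points) ----------------

raw_sernbo <- function(df, v, defaults) {
  cents <- band_cents(require_var(df, "age", "sernbo", defaults), v$age) +
    map_cents(require_var(df, "residence", "sernbo", defaults), v$residence,
              "sernbo", "residence") +
    map_cents(require_var(df, "mobility", "sernbo", defaults), v$mobility,
              "sernbo", "mobility") +
    map_cents(require_var(df, "mental_status", "sernbo", defaults),
              v$mental_status, "sernbo", "mental_status")
  cents / 100
}

raw_jiang <- function(df, v, defaults) {
  m <- "jiang"
  cents <- band_cents(require_var(df, "age", m, defaults), v$age) +
    map_cents(require_var(df, "sex", m, defaults), v$sex, m, "sex") +
    flag_cents(require_var(df, "residence", m, defaults) == "long_term_care",
               v$residence_long_term_care) +
    flag_cents(require_var(df, "malignancy", m, defaults) != "none",
               v$malignancy_any)
  for (flag in c("copd", "pneumonia", "ischemic_heart_disease", "prior_mi",
                 "arrhythmia", "chf", "malnutrition", "electrolyte_disorder",
                 "renal_disease")) {
    cents <- cents + flag_cents(require_var(df, flag, m, defaults), v[[flag]])
  }
  cents / 100
}

raw_nhfs <- function(df, v, defaults) {
  m <- "nhfs"
  cents <- band_cents(require_var(df, "age", m, defaults), v$age) +
    map_cents(require_var(df, "sex", m, defaults), v$sex, m, "sex") +
    flag_cents(require_var(df, "hemoglobin", m, defaults) <= 10,
               v$hemoglobin_le_10) +
    flag_cents(require_var(df, "cognitive_impairment", m, defaults),
               v$cognitive_impairment) +
    flag_cents(require_var(df, "residence", m, defaults) %in%
                 c("long_term_care", "rehabilitation"),
               v$institutional_residence) +
    flag_cents(require_var(df, "n_comorbidities", m, defaults) >= 2,
               v$two_or_more_comorbidities) +
    flag_cents(require_var(df, "malignancy", m, defaults) != "none",
               v$malignancy_any)
  cents / 100
}

raw_holt <- function(df, v, defaults) {
  m <- "holt"
  cents <- band_cents(require_var(df, "age", m, defaults), v$age) +
    band_cents(require_var(df, "asa_grade", m, defaults), v$asa_grade) +
    map_cents(require_var(df, "sex", m, defaults), v$sex, m, "sex") +
    map_cents(require_var(df, "residence", m, defaults), v$residence, m,
              "residence") +
    map_cents(require_var(df, "mobility", m, defaults), v$mobility, m,
              "mobility") +
    map_cents(require_var(df, "fracture_type", m, defaults), v$fracture_type,
              m, "fracture_type")
  cents / 100
}

raw_hema <- function(df, v, defaults) {
  m <- "hema"
  cents <- band_cents(require_var(df, "age", m, defaults), v$age) +
    flag_cents(require_var(df, "in_hospital_fracture", m, defaults),
               v$in_hospital_fracture) +
    flag_cents(require_var(df, "malnutrition", m, defaults), v$malnutrition) +
    flag_cents(require_var(df, "prior_mi", m, defaults), v$prior_mi) +
    flag_cents(require_var(df, "chf", m, defaults), v$chf) +
    flag_cents(require_var(df, "pneumonia", m, defaults), v$pneumonia) +
    flag_cents(require_var(df, "renal_disease", m, defaults),
               v$renal_disease) +
    flag_cents(require_var(df, "malignancy", m, defaults) != "none",
               v$malignancy_any) +
    flag_cents(require_var(df, "serum_urea", m, defaults) > 9,
               v$serum_urea_gt_9)
  cents / 100
}

raw_asagecogecc <- function(df, v, defaults) {
  m <- "asagecogecc"
  cents <- band_cents(require_var(df, "age", m, defaults), v$age) +
    band_cents(require_var(df, "cci", m, defaults), v$cci) +
    flag_cents(require_var(df, "cognitive_impairment", m, defaults),
               v$cognitive_impairment) +
    band_cents(require_var(df, "asa_grade", m, defaults), v$asa_grade) +
    map_cents(require_var(df, "sex", m, defaults), v$sex, m, "sex")
  cents / 100
}

raw_ships <- function(df, v, defaults) {
  m <- "ships"
  cents <- map_cents(require_var(df, "sex", m, defaults), v$sex, m, "sex") +
    band_cents(require_var(df, "age", m, defaults), v$age) +
    map_cents(require_var(df, "fracture_type", m, defaults), v$fracture_type,
              m, "fracture_type") +
    flag_cents(require_var(df, "nursing_care_certification", m, defaults),
               v$nursing_care_certification) +
    map_cents(require_var(df, "malignancy", m, defaults), v$malignancy, m,
              "malignancy") +
    flag_cents(require_var(df, "liver_disease_moderate_severe", m, defaults),
               v$liver_disease_moderate_severe) +
    flag_cents(require_var(df, "renal_disease", m, defaults),
               v$renal_disease) +
    flag_cents(require_var(df, "chf", m, defaults), v$chf) +
    flag_cents(require_var(df, "deficiency_anemia", m, defaults),
               v$deficiency_anemia) +
    flag_cents(require_var(df, "chronic_pulmonary_disease", m, defaults),
               v$chronic_pulmonary_disease)
  cents / 100
}

raw_score_fns <- list(sernbo = raw_sernbo, jiang = raw_jiang,
                      nhfs = raw_nhfs, holt = raw_holt, hema = raw_hema,
                      asagecogecc = raw_asagecogecc, ships = raw_ships)

# ---- probability transforms -------------------------------------------------

#' NHFS predicted 30-day mortality
#'
#' Evaluates the published NHFS logistic transform
#' `100 / (1 + exp(5.0122 - 0.481 * S))` at integer scores `S`, returning a
#' percentage. Strictly increasing in the score.
#'
#' @param score Integer NHFS score(s) in the attainable range 0-10.
#' @param config Model configuration (supplies the transform constants).
#' @return Predicted 30-day mortality in percent.
#' @examples
#' round(nhfs_probability(4), 1)  # 4.4
#' @export
nhfs_probability <- function(score, config = default_model_config()) {
  tr <- config$nhfs$transform
  if (any(is.na(score)) || any(score < 0 | score > 10)) {
    stop("NHFS score out of attainable range 0-10", call. = FALSE)
  }
  100 / (1 + exp(tr$intercept - tr$slope * score))
}

#' Holt predicted mortality
#'
#' Evaluates the Holt logistic transform
#' `1 / (1 + exp(-(intercept + score)))` on the summed model coefficients.
#' The source publication omits the intercept value, so none is shipped: the
#' transform refuses to run unconfigured rather than silently defaulting. A
#' usable 30-day intercept (-4.79) can be derived with
#' [holt_intercept_from_bounds()].
#'
#' @param score Summed Holt coefficients.
#' @param intercept Logistic intercept; required.
#' @return Predicted mortality as a fraction in (0, 1).
#' @examples
#' holt_probability(0, intercept = 0)  # 0.5
#' round(100 * holt_probability(2, intercept = -4.79), 1)  # 5.8
#' @export
holt_probability <- function(score, intercept = NULL) {
  if (is.null(intercept) || length(intercept) != 1 || is.na(intercept)) {
    stop("unconfigured transform: the Holt logistic intercept is not ",
         "published and must be supplied (see holt_intercept_from_bounds())",
         call. = FALSE)
  }
  plogis(intercept + score)
}

# predicted probability column for a panel, per the model's transform;
# NA where the model has no self-contained per-patient transform
panel_probability <- function(score, spec) {
  tr <- spec$transform
  if (is.null(tr)) return(rep(NA_real_, length(score)))
  if (identical(tr$type, "logistic_pct")) {
    return(1 / (1 + exp(tr$intercept - tr$slope * score)))
  }
  if (identical(tr$type, "logistic") && !is.null(tr$intercept)) {
    return(holt_probability(score, tr$intercept))
  }
  rep(NA_real_, length(score))
}

# ---- public calculators -----------------------------------------------------

score_one_model <- function(p, model, config = default_model_config(),
                            defaults = list()) {
  df <- as_records(p)
  spec <- get_model_spec(model, config)
  score <- raw_score_fns[[model]](df, spec$variables, defaults)
  prob <- panel_probability(score, spec)
  panel_df(df, model, score, prob, spec)
}

#' Score patients with one risk model
#'
#' Each calculator takes patient records (a `cohort`, data frame, or
#' single-record list), applies the model's weight table from the
#' configuration, and returns a score panel: one row per patient with the raw
#' score, the predicted mortality probability where the model publishes a
#' usable transform (`NA` otherwise), and the assigned risk stratum.
#'
#' Missing required variables raise a per-patient scoring error naming the
#' variable; `defaults` opts in to explicit per-variable fallback values
#' (e.g. `list(residence = "own_home")`).
#'
#' @param p Patient record(s).
#' @param config Model configuration from [load_model_config()].
#' @param defaults Named list of per-variable fallback values for missing
#'   entries.
#' @return Data frame with columns `patient_id`, `model`, `raw_score`,
#'   `predicted_prob`, `stratum`.
#' @name score_models
NULL

#' @rdname score_models
#' @export
score_sernbo <- function(p, config = default_model_config(),
                         defaults = list()) {
  score_one_model(p, "sernbo", config, defaults)
}

#' @rdname score_models
#' @export
score_jiang <- function(p, config = default_model_config(),
                        defaults = list()) {
  score_one_model(p, "jiang", config, defaults)
}

#' @rdname score_models
#' @export
score_nhfs <- function(p, config = default_model_config(),
                       defaults = list()) {
  score_one_model(p, "nhfs", config, defaults)
}

#' @rdname score_models
#' @export
score_holt <- function(p, config = default_model_config(),
                       defaults = list()) {
  score_one_model(p, "holt", config, defaults)
}

#' @rdname score_models
#' @export
score_hema <- function(p, config = default_model_config(),
                       defaults = list()) {
  score_one_model(p, "hema", config, defaults)
}

#' @rdname score_models
#' @export
score_asagecogecc <- function(p, config = default_model_config(),
                              defaults = list()) {
  score_one_model(p, "asagecogecc", config, defaults)
}

#' @rdname score_models
#' @export
score_ships <- function(p, config = default_model_config(),
                        defaults = list()) {
  score_one_model(p, "ships", config, defaults)
}

#' Score patients with a selection of models
#'
#' Applies each selected model to the records; a model that fails (e.g. a
#' required variable entirely missing) is reported in the `failures`
#' attribute rather than aborting the remaining models.
#'
#' @param p Patient record(s) (`cohort`, data frame or list).
#' @param models Character vector of model names; defaults to all seven.
#' @param config Model configuration.
#' @param defaults Per-variable fallback values, see [score_models].
#' @return Long data frame of score panels (one row per patient x model),
#'   with a `failures` attribute: named list of error messages per failed
#'   model.
#' @export
score_all <- function(p, models = NULL, config = default_model_config(),
                      defaults = list()) {
  if (is.null(models)) models <- names(config)
  unknown <- setdiff(models, names(config))
  if (length(unknown)) {
    stop("unknown model(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list()
  failures <- list()
  for (m in models) {
    res <- tryCatch(score_one_model(p, m, config, defaults),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[m]] <- conditionMessage(res)
    } else {
      out[[m]] <- res
    }
  }
  panels <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), model = character(),
               raw_score = numeric(), predicted_prob = numeric(),
               stratum = character())
  rownames(panels) <- NULL
  attr(panels, "failures") <- failures
  panels
}
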