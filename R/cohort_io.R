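# Cohort I/O: typed reading, invariant validation, eligibility filtering and
# lossless writing of patient-level tables.

# canonical field set ---------------------------------------------------------

COHORT_CATEGORICAL <- c("sex", "residence", "mobility", "mental_status",
                        "fracture_type", "malignancy")

COHORT_LOGICAL <- c("cognitive_impairment", "in_hospital_fracture",
                    "nursing_care_certification", "copd", "pneumonia",
                    "ischemic_heart_disease", "prior_mi", "arrhythmia", "chf",
                    "malnutrition", "electrolyte_disorder", "renal_disease",
                    "liver_disease_moderate_severe", "deficiency_anemia",
                    "chronic_pulmonary_disease", "treated_surgically",
                    "dead_1y", "lost_to_followup")

COHORT_INTEGER <- c("age", "asa_grade", "cci", "n_comorbidities")

COHORT_NUMERIC <- c("hemoglobin", "serum_urea", "dxa_t_score",
                    "followup_months")

COHORT_OPTIONAL <- c("dxa_t_score", "periprosthetic")

cohort_fields <- function() {
  c("patient_id", COHORT_INTEGER, COHORT_CATEGORICAL, COHORT_LOGICAL,
    COHORT_NUMERIC, "admission_date", "periprosthetic")
}

#' Default cohort CSV schema
#'
#' Loads the packaged column-mapping/encoding schema used by [read_cohort()].
#' The schema is a plain list with `columns` (canonical field -> CSV header)
#' and `levels` (per categorical field, raw value -> canonical level); copy
#' and edit it to remap a local export format.
#'
#' @param path Path to a schema JSON; defaults to the packaged schema.
#' @return A list with elements `columns` and `levels`.
#' @export
default_cohort_schema <- function(path = system.file("extdata",
                                                     "cohort_schema.json",
                                                     package = "fragscore",
                                                     mustWork = TRUE)) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# ---- constructor ------------------------------------------------------------

#' Construct a cohort object
#'
#' Wraps a validated patient-level data frame together with a provenance tag.
#' Record invariants (enumerated categorical levels, non-negative ages and
#' follow-up, ASA 1-5, `dead_1y` missing exactly for lost-to-follow-up
#' patients) are enforced at construction.
#'
#' @param records Data frame of patient records in canonical fields.
#' @param provenance Free-text source tag.
#' @return An object of class `cohort`: a list with `records` and
#'   `provenance`.
#' @export
as_cohort <- function(records, provenance = "unspecified") {
  records <- validate_records(records)
  structure(list(records = records, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  r <- x$records
  cat("<cohort> ", nrow(r), " patients (", x$provenance, ")\n", sep = "")
  if (nrow(r) > 0) {
    cat("  age median ", stats::median(r$age),
        "; female ", sprintf("%.1f%%", 100 * mean(r$sex == "female")),
        "; 1-year deaths ", sum(r$dead_1y, na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}

validate_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- setdiff(cohort_fields(), COHORT_OPTIONAL)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"periprosthetic" %in% names(df)) df$periprosthetic <- FALSE
  if (!"dxa_t_score" %in% names(df)) df$dxa_t_score <- NA_real_

  levels_of <- list(
    sex = c("male", "female"),
    residence = c("own_home", "sheltered_or_assisted", "long_term_care",
                  "rehabilitation", "acute_ward"),
    mobility = c("no_aids", "one_aid", "two_aids_or_frame",
                 "requires_accompaniment", "unable_to_walk"),
    mental_status = c("alert", "slight_confusion"),
    fracture_type = c("femoral_neck", "pertrochanteric", "subtrochanteric",
                      "pathological"),
    malignancy = c("none", "skin", "other", "metastatic"))
  for (v in names(levels_of)) {
    bad <- which(!is.na(df[[v]]) & !df[[v]] %in% levels_of[[v]])
    if (length(bad)) {
      stop("cohort record error: row ", bad[1], ": '", df[[v]][bad[1]],
           "' is not a valid level of ", v, call. = FALSE)
    }
  }
  for (v in c(COHORT_LOGICAL, "periprosthetic")) df[[v]] <- as.logical(df[[v]])
  for (v in COHORT_INTEGER) df[[v]] <- as.integer(df[[v]])
  for (v in COHORT_NUMERIC) df[[v]] <- as.numeric(df[[v]])
  df$patient_id <- as.character(df$patient_id)
  df$admission_date <- parse_iso_date(df$admission_date)

  check <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad)) {
      stop("cohort record error: row ", bad[1], ": ", msg, call. = FALSE)
    }
  }
  check(!is.na(df$age) & df$age >= 0, "age must be a non-negative integer")
  check(!is.na(df$asa_grade) & df$asa_grade %in% 1:5, "asa_grade must be 1-5")
  check(is.na(df$hemoglobin) | df$hemoglobin > 0,
        "hemoglobin must be positive when present")
  check(!is.na(df$followup_months) & df$followup_months >= 0,
        "followup_months must be >= 0")
  check(!is.na(df$cci) & df$cci >= 0, "cci must be >= 0")
  check(!is.na(df$n_comorbidities) & df$n_comorbidities >= 0,
        "n_comorbidities must be >= 0")
  check(is.na(df$dead_1y) == df$lost_to_followup,
        "dead_1y must be missing exactly when lost_to_followup")
  rownames(df) <- NULL
  df
}

parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop("cohort record error: row ", bad[1], ": admission_date '", x[bad[1]],
         "' is not an ISO-8601 date (YYYY-MM-DD)", call. = FALSE)
  }
  out
}

# ---- read / write -----------------------------------------------------------

#' Read a patient-level cohort CSV
#'
#' Reads, remaps and type-validates a cohort table. Column names and
#' categorical encodings are resolved through a schema
#' ([default_cohort_schema()]); unknown categorical values raise row-level
#' errors, missing required columns raise a schema error naming the column.
#'
#' @param path CSV file path.
#' @param schema Column-mapping schema list.
#' @param provenance Source tag stored on the cohort; defaults to the path.
#' @return A [`cohort`][as_cohort] object.
#' @export
read_cohort <- function(path, schema = default_cohort_schema(),
                        provenance = path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("NA", ""))
  colmap <- schema$columns
  required <- setdiff(names(colmap), COHORT_OPTIONAL)
  absent <- required[!unlist(colmap[required]) %in% names(raw)]
  if (length(absent)) {
    stop("cohort schema error: missing required column(s): ",
         paste(unlist(colmap[absent]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(colmap)) {
    csv_name <- colmap[[canon]]
    if (csv_name %in% names(raw)) df[[canon]] <- raw[[csv_name]]
  }
  # categorical recoding with row-level diagnostics
  for (v in intersect(names(schema$levels), names(df))) {
    map <- schema$levels[[v]]
    vals <- as.character(df[[v]])
    known <- vals %in% names(map)
    bad <- which(!is.na(vals) & !known)
    if (length(bad)) {
      stop("cohort read error: row ", bad[1], ": value '", vals[bad[1]],
           "' of column '", colmap[[v]], "' has no schema mapping for ", v,
           call. = FALSE)
    }
    df[[v]] <- ifelse(is.na(vals), NA_character_,
                      unlist(map)[match(vals, names(map))])
  }
  as_cohort(df, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Writes canonical columns so that `read_cohort(write_cohort(x))` is the
#' identity on every field.
#'
#' @param cohort A `cohort` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- cohort$records
  df$admission_date <- format(df$admission_date, "%Y-%m-%d")
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write cohort to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

# ---- eligibility ------------------------------------------------------------

#' Eligibility rules for the validation cohort
#'
#' The study design enrols surgically treated fragility hip fracture patients
#' aged 60 or over with densitometric osteoporosis (DXA T-score <= -2.5),
#' excludes periprosthetic and pathological fractures, keeps the first
#' admission when a patient fractures the contralateral hip within the study
#' window, and drops patients lost to follow-up.
#'
#' @param min_age Minimum age in years.
#' @param max_t_score Maximum DXA T-score (inclusive); set
#'   `enforce_t_score = FALSE` to disable when T-scores were not recorded.
#' @param enforce_t_score Apply the T-score rule (records with a missing
#'   T-score are never excluded by it).
#' @param require_surgery Exclude conservatively treated patients.
#' @param exclude_fracture_types Fracture types excluded outright.
#' @param exclude_periprosthetic Exclude records flagged periprosthetic.
#' @param drop_lost_to_followup Exclude patients lost to follow-up.
#' @return A list of rules for [filter_eligible()].
#' @export
eligibility_rules <- function(min_age = 60,
                              max_t_score = -2.5,
                              enforce_t_score = TRUE,
                              require_surgery = TRUE,
                              exclude_fracture_types = "pathological",
                              exclude_periprosthetic = TRUE,
                              drop_lost_to_followup = TRUE) {
  list(min_age = min_age, max_t_score = max_t_score,
       enforce_t_score = enforce_t_score, require_surgery = require_surgery,
       exclude_fracture_types = exclude_fracture_types,
       exclude_periprosthetic = exclude_periprosthetic,
       drop_lost_to_followup = drop_lost_to_followup)
}

#' Apply eligibility rules to a cohort
#'
#' Filters a cohort per the study's eligibility rules and returns both the
#' eligible cohort and a per-rule exclusion log. Each excluded record is
#' counted once, under the first rule (in the documented order) that removes
#' it, so log counts plus the eligible count always equal the input count.
#' Duplicate `patient_id`s keep the earliest admission.
#'
#' @param cohort A `cohort` object.
#' @param rules From [eligibility_rules()].
#' @return A list with `cohort` (eligible records) and `log` (data frame of
#'   rule, n_excluded).
#' @export
filter_eligible <- function(cohort, rules = eligibility_rules()) {
  stopifnot(inherits(cohort, "cohort"))
  df <- cohort$records
  n <- nrow(df)
  excluded <- rep(NA_character_, n)
  mark <- function(cond, rule) {
    hit <- which(cond & is.na(excluded))
    excluded[hit] <<- rule
  }
  mark(df$age < rules$min_age, "below_min_age")
  if (isTRUE(rules$require_surgery)) {
    mark(!df$treated_surgically, "non_surgical")
  }
  if (isTRUE(rules$enforce_t_score)) {
    mark(!is.na(df$dxa_t_score) & df$dxa_t_score > rules$max_t_score,
         "t_score_above_threshold")
  }
  mark(df$fracture_type %in% rules$exclude_fracture_types,
       "excluded_fracture_type")
  if (isTRUE(rules$exclude_periprosthetic)) {
    mark(!is.na(df$periprosthetic) & df$periprosthetic, "periprosthetic")
  }
  if (isTRUE(rules$drop_lost_to_followup)) {
    mark(df$lost_to_followup, "lost_to_followup")
  }
  # first admission per patient among still-eligible records
  keep <- is.na(excluded)
  idx <- which(keep)
  if (length(idx)) {
    ord <- idx[order(df$admission_date[idx], idx)]
    dup <- ord[duplicated(df$patient_id[ord])]
    excluded[dup] <- "later_admission_of_duplicate_patient"
  }
  eligible <- df[is.na(excluded), , drop = FALSE]
  rownames(eligible) <- NULL
  rule_order <- c("below_min_age", "non_surgical", "t_score_above_threshold",
                  "excluded_fracture_type", "periprosthetic",
                  "lost_to_followup", "later_admission_of_duplicate_patient")
  tab <- table(factor(excluded, levels = rule_order))
  log <- data.frame(rule = names(tab), n_excluded = as.integer(tab),
                    stringsAsFactors = FALSE)
  log <- log[log$n_excluded > 0, , drop = FALSE]
  rownames(log) <- NULL
  list(cohort = as_cohort(eligible,
                          provenance = paste0(cohort$provenance,
                                              " [eligible]")),
       log = log)
}
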