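# End-to-end orchestration: simulate or load a cohort, score the selected
# models, validate each (discrimination, calibration, classification,
# stratification), compare AUCs pairwise, and render tabular reports.

#' Pipeline run configuration
#'
#' Exactly one input source: a cohort CSV (`input_csv`) or a simulation
#' configuration (`sim`).
#'
#' @param input_csv Path to a cohort CSV, or `NULL` to simulate.
#' @param sim A [cohort_sim_config()], used when `input_csv` is `NULL`.
#' @param models Model selection (default: all configured models).
#' @param model_config Model configuration from [load_model_config()].
#' @param schema Cohort CSV schema for [read_cohort()].
#' @param eligibility Eligibility rules; `NULL` skips filtering.
#' @param threshold_rule `"youden"` or an explicit numeric threshold applied
#'   to every model's raw (orientation-corrected) score.
#' @param hl_groups Nominal Hosmer-Lemeshow group count.
#' @param representative Representative value for interval-valued stratum
#'   predictions ("upper", "lower", "mid").
#' @param out_dir Output directory; `NULL` returns results without writing.
#' @param seed Seed recorded in the manifest (the simulation seed comes from
#'   `sim`).
#' @return List of class `frag_run_config`.
#' @export
run_config <- function(input_csv = NULL, sim = NULL, models = NULL,
                       model_config = default_model_config(),
                       schema = default_cohort_schema(),
                       eligibility = eligibility_rules(enforce_t_score = FALSE),
                       threshold_rule = "youden", hl_groups = 10,
                       representative = "upper", out_dir = NULL, seed = 1) {
  if (!is.null(input_csv) && !is.null(sim)) {
    stop("exactly one input source: give input_csv or sim, not both",
         call. = FALSE)
  }
  if (is.null(input_csv) && is.null(sim)) sim <- cohort_sim_config(seed = seed)
  if (is.null(models)) models <- names(model_config)
  structure(list(input_csv = input_csv, sim = sim, models = models,
                 model_config = model_config, schema = schema,
                 eligibility = eligibility, threshold_rule = threshold_rule,
                 hl_groups = hl_groups, representative = representative,
                 out_dir = out_dir, seed = seed),
            class = "frag_run_config")
}

# predicted probabilities for calibration analyses, per the model's
# configured probability source; returns list(prob, source_label)
model_probabilities <- function(panel, outcomes, spec,
                                representative = "upper") {
  src <- spec$probability_source
  if (identical(src, "formula") || (!is.null(spec$transform) &&
                                    identical(spec$transform$type,
                                              "logistic") &&
                                    !is.null(spec$transform$intercept))) {
    if (!anyNA(panel$predicted_prob)) {
      return(list(prob = panel$predicted_prob, source = "formula"))
    }
  }
  if (identical(src, "strata")) {
    pred <- stratum_predicted(spec, representative)
    if (!anyNA(pred)) {
      return(list(prob = unname(pred[panel$stratum]) / 100,
                  source = paste0("stratum_", representative)))
    }
  }
  # in-sample logistic recalibration of the raw score (labelled as such):
  # used where the source publishes no usable probabilities (Sernbo; Holt
  # until an intercept is configured)
  X <- cbind(1, panel$raw_score)
  fit <- logistic_fit(X, as.integer(as.logical(outcomes)))
  list(prob = plogis(drop(X %*% fit$coef)), source = "recalibrated")
}

# orientation-corrected score: higher always = higher predicted mortality
oriented_scores <- function(panel, spec) {
  if (identical(spec$orientation, "descending")) -panel$raw_score else
    panel$raw_score
}

#' Validate one model's scores against observed outcomes
#'
#' Builds the full validation report for one score panel: AUC with DeLong CI
#' on the score as published and orientation-corrected, Hosmer-Lemeshow
#' test and calibration slope/intercept on the model's predicted
#' probabilities (source recorded in the metadata), confusion metrics at the
#' configured threshold (computed on the orientation-corrected score), and
#' the predicted-versus-observed stratum table.
#'
#' @param panel Score panel for one model.
#' @param outcomes Binary 1-year death indicator aligned with the panel.
#' @param spec Model specification or name.
#' @param threshold_rule `"youden"` or numeric.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @param representative Stratum-interval representative.
#' @return List of class `validation_report`.
#' @export
validate_model <- function(panel, outcomes, spec, threshold_rule = "youden",
                           hl_groups = 10, representative = "upper") {
  if (is.character(spec)) spec <- get_model_spec(spec)
  y <- as.integer(as.logical(outcomes))
  stopifnot(nrow(panel) == length(y))
  osc <- oriented_scores(panel, spec)
  auc_pub <- roc_auc(panel$raw_score, y)
  auc_cor <- if (identical(spec$orientation, "descending")) roc_auc(osc, y)
             else auc_pub
  pr <- model_probabilities(panel, y, spec, representative)
  hl <- hosmer_lemeshow(pr$prob, y, groups = hl_groups)
  cal <- calibration_slope(pr$prob, y)
  cm <- confusion_metrics(osc, y, threshold = threshold_rule)
  st <- stratum_table(panel, y, spec, representative)
  structure(list(
    model = spec$name, label = spec$label,
    n = length(y), n_deaths = sum(y),
    auc = auc_pub$auc, auc_ci = auc_pub$ci,
    auc_oriented = auc_cor$auc, auc_oriented_ci = auc_cor$ci,
    orientation = spec$orientation,
    hl_statistic = hl$statistic, hl_df = hl$df, hl_p = hl$p,
    hl_groups_used = hl$groups_used, hl_degenerate = hl$degenerate,
    calibration_slope = cal$slope, calibration_slope_ci = cal$slope_ci,
    calibration_intercept = cal$intercept,
    calibration_intercept_ci = cal$intercept_ci,
    calibration_flagged = cal$flagged,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    ppv = cm$ppv, npv = cm$npv, threshold = cm$threshold,
    strata = st,
    metadata = list(
      probability_source = pr$source,
      adaptations = if (!is.null(spec$notes)) spec$notes else NULL)),
    class = "validation_report")
}

#' Pairwise DeLong comparison matrix
#'
#' Two-sided DeLong p-values for every model pair, computed on
#' orientation-corrected scores so that every comparison is
#' higher-score-worse on both sides. The diagonal is 1 by construction.
#'
#' @param panels Long panel data frame for several models.
#' @param outcomes Binary outcomes aligned with each model's rows.
#' @param config Model configuration.
#' @return Square matrix of p-values with model-name dimnames.
#' @export
delong_matrix <- function(panels, outcomes, config = default_model_config()) {
  models <- unique(panels$model)
  y <- as.integer(as.logical(outcomes))
  score_of <- lapply(models, function(m) {
    sub <- panels[panels$model == m, , drop = FALSE]
    oriented_scores(sub, get_model_spec(m, config))
  })
  names(score_of) <- models
  k <- length(models)
  p <- matrix(1, k, k, dimnames = list(models, models))
  if (k < 2) return(p)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- delong_test(score_of[[i]], score_of[[j]], y)
      p[i, j] <- p[j, i] <- d$p
    }
  }
  p
}

#' Run the full validation pipeline
#'
#' Simulates or reads a cohort, applies eligibility filtering, scores the
#' selected models, validates each against observed 1-year mortality,
#' compares AUCs pairwise, builds the stratum tables and the Kaplan-Meier
#' curve, and (when `out_dir` is set) writes the report bundle: panels CSV,
#' one validation-report JSON per model, the DeLong p-value matrix, rendered
#' performance and stratification tables (TSV), the KM curve TSV, and a run
#' manifest. Outputs are deterministic given the configuration, so a rerun
#' with the same manifest reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `cohort`, `exclusion_log`, `panels`,
#'   `reports`, `delong`, `km`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "frag_run_config"))
  cohort <- if (!is.null(config$input_csv)) {
    read_cohort(config$input_csv, schema = config$schema)
  } else {
    generate_cohort(config$sim)
  }
  exclusion_log <- NULL
  if (!is.null(config$eligibility)) {
    flt <- filter_eligible(cohort, config$eligibility)
    exclusion_log <- flt$log
    cohort <- flt$cohort
  }
  rec <- cohort$records
  outcomes <- as.integer(rec$dead_1y)

  panels <- score_all(rec, models = config$models,
                      config = config$model_config)
  failures <- attr(panels, "failures")
  scored_models <- unique(panels$model)

  reports <- lapply(scored_models, function(m) {
    validate_model(panels[panels$model == m, , drop = FALSE], outcomes,
                   get_model_spec(m, config$model_config),
                   threshold_rule = config$threshold_rule,
                   hl_groups = config$hl_groups,
                   representative = config$representative)
  })
  names(reports) <- scored_models

  dl <- if (length(scored_models) > 1) {
    delong_matrix(panels, outcomes, config$model_config)
  } else NULL

  event <- if ("event" %in% names(rec)) as.integer(rec$event) else outcomes
  km <- km_estimate(rec$followup_months, event)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fragscore")),
    seed = config$seed,
    input = if (!is.null(config$input_csv)) config$input_csv else
      paste0("simulated n=", config$sim$n, " seed=", config$sim$seed),
    models = config$models,
    threshold_rule = config$threshold_rule,
    hl_groups = config$hl_groups,
    representative = config$representative,
    n_eligible = nrow(rec),
    exclusions = exclusion_log,
    scoring_failures = failures)

  bundle <- list(cohort = cohort, exclusion_log = exclusion_log,
                 panels = panels, reports = reports, delong = dl, km = km,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write.csv(bundle$panels, fp("panels.csv"), row.names = FALSE)
  for (m in names(bundle$reports)) {
    rep <- bundle$reports[[m]]
    jsonlite::write_json(rep[setdiff(names(rep), "strata")],
                         fp(paste0("report_", m, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(bundle$delong)) {
    write.csv(as.data.frame(bundle$delong), fp("delong_matrix.csv"))
  }
  writeLines(render_table3(bundle$reports), fp("table3.tsv"))
  writeLines(render_table4(bundle$reports), fp("table4.tsv"))
  write_km_curve(bundle$km, fp("km_curve.tsv"))
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Render the model-performance table
#'
#' One row per model: AUC (95% CI), Hosmer-Lemeshow p, calibration slope
#' (95% CI), sensitivity/specificity/PPV/NPV at the chosen threshold.
#' Display rounding is two decimals for AUC and slope, one for percentages;
#' the underlying report objects keep full precision.
#'
#' @param reports Named list of `validation_report`s.
#' @return Character vector of TSV lines.
#' @export
render_table3 <- function(reports) {
  header <- paste("model", "auc_95ci", "hl_p", "calibration_slope_95ci",
                  "sensitivity", "specificity", "ppv", "npv", sep = "\t")
  rows <- vapply(reports, function(r) {
    paste(r$label,
          sprintf("%s (%s-%s)", fmt2(r$auc), fmt2(r$auc_ci[1]),
                  fmt2(r$auc_ci[2])),
          fmt2(r$hl_p),
          sprintf("%s (%s, %s)", fmt2(r$calibration_slope),
                  fmt2(r$calibration_slope_ci[1]),
                  fmt2(r$calibration_slope_ci[2])),
          fmt2(r$sensitivity), fmt2(r$specificity), fmt2(r$ppv),
          fmt2(r$npv), sep = "\t")
  }, character(1))
  c(header, unname(rows))
}

#' Render the risk-stratification table
#'
#' One row per model and stratum: nominal predicted mortality, n (%),
#' observed mortality and stratum accuracy, with empty strata shown as
#' "None" (cohorts may lack, e.g., a low-risk group).
#'
#' @param reports Named list of `validation_report`s.
#' @return Character vector of TSV lines.
#' @export
render_table4 <- function(reports) {
  header <- paste("model", "stratum", "predicted_pct", "n", "pct",
                  "observed_pct", "accuracy_pct", sep = "\t")
  rows <- unlist(lapply(reports, function(r) {
    st <- r$strata
    vapply(seq_len(nrow(st)), function(i) {
      empty <- st$n[i] == 0
      paste(r$label, st$stratum[i], fmt1(st$predicted_pct[i]),
            if (empty) "None" else st$n[i],
            if (empty) "None" else fmt1(st$pct[i]),
            if (empty) "None" else fmt1(st$observed_pct[i]),
            if (empty || is.na(st$accuracy_pct[i])) "None" else
              fmt1(st$accuracy_pct[i]),
            sep = "\t")
    }, character(1))
  }), use.names = FALSE)
  c(header, rows)
}
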