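#' Load a risk-model configuration
#'
#' Reads the YAML configuration holding, for each of the seven risk models,
#' its variable weights, probability transform, risk-stratum cutoffs with
#' nominal predicted mortalities, score orientation, and the probability
#' source used for calibration analyses. The packaged default reproduces the
#' published weight tables and stratum cutoffs; it can be copied, edited (for
#' instance to correct a weight against an original model publication or to
#' set the Holt logistic intercept) and passed back in.
#'
#' Validation is structural and scientific: every stratum list must be
#' ordered, non-overlapping, and must cover the model's attainable score set,
#' which is enumerated by brute force from the weight table
#' (see [enumerate_scores()]).
#'
#' @param path Path to a YAML model configuration. Defaults to the packaged
#'   configuration.
#' @return A named list of model specifications (class `frag_config`), one
#'   element per model, each with elements `name`, `label`, `orientation`,
#'   `probability_source`, `variables`, `strata` and optionally `transform`.
#' @examples
#' cfg <- load_model_config()
#' names(cfg)
#' cfg$nhfs$strata
#' @export
load_model_config <- function(path = default_config_path()) {
  if (!file.exists(path)) {
    stop("model config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$models)) {
    stop("config error: top-level 'models' entry missing", call. = FALSE)
  }
  cfg <- raw$models
  for (nm in names(cfg)) {
    cfg[[nm]]$name <- nm
    validate_model_spec(cfg[[nm]])
  }
  structure(cfg, class = "frag_config", version = raw$version)
}

default_config_path <- function() {
  system.file("extdata", "model_config.yaml", package = "fragscore",
              mustWork = TRUE)
}

# memoised default config (weights never change within a session)
.frag_env <- new.env(parent = emptyenv())

default_model_config <- function() {
  if (is.null(.frag_env$config)) {
    .frag_env$config <- load_model_config()
  }
  .frag_env$config
}

# ---- structural validation -------------------------------------------------

validate_model_spec <- function(spec) {
  name <- spec$name
  if (is.null(spec$variables) || is.null(spec$strata)) {
    stop("config error (", name, "): 'variables' and 'strata' are required",
         call. = FALSE)
  }
  if (!spec$orientation %in% c("ascending", "descending")) {
    stop("config error (", name, "): orientation must be ascending/descending",
         call. = FALSE)
  }
  strata <- spec$strata
  lo <- vapply(strata, function(s) as.numeric(s$min), numeric(1))
  hi <- vapply(strata, function(s) as.numeric(s$max), numeric(1))
  if (any(diff(lo) <= 0)) {
    stop("config error (", name, "): strata must be in increasing score order",
         call. = FALSE)
  }
  # overlap check on closed/open interval bounds
  for (i in seq_along(strata)[-1]) {
    open_prev <- isTRUE(strata[[i - 1]]$open_max)
    open_this <- isTRUE(strata[[i]]$open_min)
    if (hi[i - 1] > lo[i] + 1e-9 ||
        (abs(hi[i - 1] - lo[i]) < 1e-9 && !open_prev && !open_this)) {
      stop("config error (", name, "): overlapping strata '",
           strata[[i - 1]]$label, "' and '", strata[[i]]$label, "'",
           call. = FALSE)
    }
  }
  # coverage of the attainable score set
  attainable <- enumerate_scores(spec)
  labels <- stratify_score(attainable, spec)
  if (anyNA(labels)) {
    gap <- attainable[is.na(labels)]
    stop("config error (", name, "): strata do not cover attainable score(s) ",
         paste(utils::head(gap, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Enumerate a model's attainable raw scores
#'
#' Brute-force enumeration of every total score a model can produce, from the
#' per-variable weight alternatives in its configuration. Weights are
#' accumulated in integer hundredths so decimal-weighted models (Holt, HEMA)
#' enumerate exactly.
#'
#' @param spec One model specification from [load_model_config()], or a model
#'   name (resolved against the packaged default).
#' @return Sorted numeric vector of attainable total scores.
#' @examples
#' enumerate_scores("sernbo")  # 8 11 14 17 20
#' @export
enumerate_scores <- function(spec) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  alts <- lapply(spec$variables, variable_weight_alternatives)
  cents <- lapply(alts, function(w) as.integer(round(100 * w)))
  total <- Reduce(function(acc, w) unique(as.vector(outer(acc, w, "+"))),
                  cents, accumulate = FALSE)
  sort(total) / 100
}

# possible weight values one variable can contribute
variable_weight_alternatives <- function(v) {
  if (is.numeric(v) && length(v) == 1L) {
    return(c(0, v))                       # boolean flag with a single weight
  }
  if (is.list(v) && !is.null(v$breaks)) {
    return(as.numeric(v$weights))         # banded numeric variable
  }
  as.numeric(unlist(v))                   # categorical map
}

#' Assign risk strata to raw scores
#'
#' Maps raw scores onto the model's ordered risk strata. Interval bounds are
#' inclusive unless flagged open (`open_min`/`open_max`), which the Holt
#' model's `<1` / `>2` cutoffs require. Comparisons are made at a 1e-9
#' tolerance; scores are exact hundredths so boundary assignment is stable.
#'
#' @param score Numeric vector of raw scores.
#' @param spec Model specification or model name.
#' @return Character vector of stratum labels (`NA` for uncovered scores,
#'   which the packaged configurations never produce for attainable scores).
#' @export
stratify_score <- function(score, spec) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  eps <- 1e-9
  out <- rep(NA_character_, length(score))
  for (s in spec$strata) {
    lo <- as.numeric(s$min); hi <- as.numeric(s$max)
    ok_lo <- if (isTRUE(s$open_min)) score > lo + eps else score >= lo - eps
    ok_hi <- if (isTRUE(s$open_max)) score < hi - eps else score <= hi + eps
    hit <- ok_lo & ok_hi & is.na(out)
    out[hit] <- s$label
  }
  out
}

get_model_spec <- function(model, config = default_model_config()) {
  if (!model %in% names(config)) {
    stop("unknown model '", model, "'; available: ",
         paste(names(config), collapse = ", "), call. = FALSE)
  }
  config[[model]]
}

#' Stratum-level nominal predicted mortality
#'
#' Returns the representative predicted mortality (in percent) for each
#' stratum of a model. Interval-valued predictions (e.g. NHFS high risk
#' 10.7-33.6%) are collapsed to a representative value: the upper bound by
#' default, configurable because the source tables are not consistent about
#' which bound they use.
#'
#' @param spec Model specification or name.
#' @param representative One of "upper", "lower", "mid".
#' @return Named numeric vector (percent), `NA` where the model publishes no
#'   predicted mortality (Sernbo).
#' @export
stratum_predicted <- function(spec, representative = c("upper", "lower", "mid")) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  representative <- match.arg(representative)
  vapply(spec$strata, function(s) {
    p <- s$predicted
    if (is.null(p)) return(NA_real_)
    p <- as.numeric(p)
    if (length(p) == 1L) return(p)
    switch(representative,
           upper = max(p), lower = min(p), mid = mean(p))
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(vapply(spec$strata, `[[`, "", "label"))
}

#' Derive the Holt logistic intercept from published stratum bounds
#'
#' The Holt model's 30-day mortality transform is logistic in the summed
#' coefficients, but its intercept is not published. The high-risk stratum
#' bounds pair scores with mortalities (score 2 with 5.8%, score 4.92 with
#' 53.2%), and inverting the logistic at each pair recovers the intercept;
#' this helper averages the two inversions and rounds. The result (-4.79)
#' reproduces both printed bounds to one decimal.
#'
#' @param scores Scores at the published bounds.
#' @param mortality_pct Mortalities (percent) at those scores.
#' @param digits Rounding applied to the result; `NULL` for none.
#' @return The intercept for [holt_probability()].
#' @examples
#' holt_intercept_from_bounds()  # -4.79
#' @export
holt_intercept_from_bounds <- function(scores = c(2, 4.92),
                                       mortality_pct = c(5.8, 53.2),
                                       digits = 2) {
  stopifnot(length(scores) == length(mortality_pct), length(scores) >= 1)
  est <- mean(qlogis(mortality_pct / 100) - scores)
  if (!is.null(digits)) est <- round(est, digits)
  est
}
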