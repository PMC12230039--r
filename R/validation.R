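# Discrimination, calibration, classification and stratification statistics,
# implemented from first principles (pROC serves only as an independent
# cross-check in the test suite).

check_binary_outcome <- function(outcomes) {
  y <- as.integer(as.logical(outcomes))
  if (anyNA(y)) stop("outcomes contain missing values", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  y
}

# DeLong placement values (Sun & Xu fast formulation via midranks):
# V10_i = fraction of controls ranked below case i (ties half),
# V01_j = fraction of cases ranked above control j (ties half).
delong_placements <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_cases <- rank(cases, ties.method = "average")
  r_controls <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_controls) / m
  list(v10 = v10, v01 = v01, auc = sum(r_all[seq_len(m)] - r_cases) / (m * n),
       m = m, n = n)
}

#' ROC AUC with DeLong confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic with
#' tie correction (tied case/control pairs count one half), with a 95%
#' confidence interval from the DeLong placement-value variance and a normal
#' approximation, truncated to `[0, 1]`.
#'
#' @param scores Numeric scores (higher = predicted higher mortality, unless
#'   the model is oriented otherwise; the AUC is computed on the scores as
#'   given).
#' @param outcomes Binary outcomes (death = 1/TRUE).
#' @param conf_level Confidence level for the interval.
#' @return List with `auc`, `ci` (length-2 vector), `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, outcomes, conf_level = 0.95) {
  y <- check_binary_outcome(outcomes)
  stopifnot(length(scores) == length(y))
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  pl <- delong_placements(scores, y)
  v <- var(pl$v10) / pl$m + var(pl$v01) / pl$n
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * se, 0), 1)
  list(auc = pl$auc, ci = ci, se = se, n_pos = pl$m, n_neg = pl$n)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same patients using the
#' DeLong placement-value covariance; returns the two AUCs, the z statistic
#' on their difference, and the two-sided p-value. Identical scores give
#' z = 0, p = 1 by convention (the variance of the difference is zero).
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param outcomes Binary outcomes shared by both scores.
#' @return List with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, outcomes) {
  y <- check_binary_outcome(outcomes)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("scores_a, scores_b and outcomes must have equal length",
         call. = FALSE)
  }
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  v <- var(pa$v10 - pb$v10) / pa$m + var(pa$v01 - pb$v01) / pa$n
  if (v <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Bins patients into quantile groups of predicted risk (ties are kept in a
#' single bin, so piecewise-constant predictions from stratum-level
#' probabilities yield fewer effective groups), collapses groups whose
#' expected deaths or expected survivors are zero into their neighbour, and
#' computes the chi-square statistic over deaths and survivors.
#'
#' Degrees of freedom follow the external-validation convention: the
#' predictions are taken as fixed (none of their parameters were estimated on
#' these data), so the statistic is referred to chi-square with `effective
#' groups` degrees of freedom; under this reference the test holds its
#' nominal type-I error when outcomes truly follow the predictions.
#' `fit_adjusted = TRUE` switches to the classical `groups - 2` reference for
#' predictions fit on the same data.
#'
#' @param predicted Predicted probabilities in `[0, 1]`.
#' @param outcomes Binary outcomes.
#' @param groups Nominal number of quantile groups (default 10).
#' @param fit_adjusted Use `groups - 2` degrees of freedom (development-data
#'   convention).
#' @return List with `statistic`, `df`, `p`, `groups_used`, `table` (per-bin
#'   observed/expected counts) and `degenerate` (TRUE when too few effective
#'   groups remain, in which case `p` is `NA`).
#' @export
hosmer_lemeshow <- function(predicted, outcomes, groups = 10,
                            fit_adjusted = FALSE) {
  y <- as.integer(as.logical(outcomes))
  if (anyNA(predicted) || any(predicted < 0 | predicted > 1)) {
    stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  }
  n <- length(predicted)
  stopifnot(length(y) == n)
  if (n < groups) stop("need at least as many observations as groups",
                       call. = FALSE)
  uq <- sort(unique(predicted))
  if (length(uq) < 2) {
    # all predictions identical: no grouping possible
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                groups_used = 1L, table = NULL, degenerate = TRUE))
  }
  if (length(uq) <= groups) {
    # heavily tied predictions (e.g. piecewise-constant stratum values):
    # one bin per distinct value
    bin <- match(predicted, uq)
  } else {
    breaks <- unique(quantile(predicted, probs = seq(0, 1, length.out =
                                                       groups + 1)))
    bin <- cut(predicted, breaks = breaks, include.lowest = TRUE,
               labels = FALSE)
  }
  tab <- data.frame(
    n = as.vector(tapply(y, bin, length)),
    o1 = as.vector(tapply(y, bin, sum)),
    e1 = as.vector(tapply(predicted, bin, sum)))
  # collapse bins with zero expected deaths or survivors into a neighbour
  repeat {
    e0 <- tab$n - tab$e1
    bad <- which(tab$e1 <= .Machine$double.eps | e0 <= .Machine$double.eps)
    if (!length(bad) || nrow(tab) <= 1) break
    i <- bad[1]
    j <- if (i == 1) 2L else i - 1L
    tab[j, ] <- tab[j, ] + tab[i, ]
    tab <- tab[-i, , drop = FALSE]
  }
  g <- nrow(tab)
  e0 <- tab$n - tab$e1
  o0 <- tab$n - tab$o1
  statistic <- sum((tab$o1 - tab$e1)^2 / tab$e1 + (o0 - e0)^2 / e0)
  df <- if (fit_adjusted) g - 2L else g
  degenerate <- df < 1L || g < 2L
  p <- if (degenerate) NA_real_ else pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p = p, groups_used = g,
       table = tab, degenerate = degenerate)
}

# internal Newton-Raphson logistic fit: y ~ X (with intercept column already
# in X); returns coefficients, covariance, convergence flag
logistic_fit <- function(X, y, tol = 1e-8, max_iter = 50L) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) break
    beta <- beta + as.numeric(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  vcov <- tryCatch(solve(crossprod(X, X * (plogis(drop(X %*% beta)) *
                                             (1 - plogis(drop(X %*% beta)))))),
                   error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(coef = beta, vcov = vcov, converged = converged)
}

#' Calibration slope and intercept
#'
#' Logistic regression of the outcome on the logit of the predicted
#' probability (predictions clipped to `[1e-6, 1 - 1e-6]` before the logit),
#' fit by Newton-Raphson (tolerance 1e-8, at most 50 iterations). The slope
#' is 1 for perfectly calibrated predictions; slopes below 1 indicate
#' overdispersed (overconfident) predictions. Wald 95% confidence intervals
#' come from the inverse Fisher information. Degenerate inputs (constant
#' predictions, separation, non-convergence) return a flagged result rather
#' than an error.
#'
#' @param predicted Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param conf_level Confidence level for the Wald intervals.
#' @return List with `slope`, `slope_ci`, `intercept`, `intercept_ci`,
#'   `converged`, `flagged`, `message`.
#' @export
calibration_slope <- function(predicted, outcomes, conf_level = 0.95) {
  y <- as.integer(as.logical(outcomes))
  stopifnot(length(predicted) == length(y))
  if (anyNA(predicted)) stop("predicted contains missing values",
                             call. = FALSE)
  lp <- qlogis(pmin(pmax(predicted, 1e-6), 1 - 1e-6))
  flagged_result <- function(msg) {
    list(slope = NA_real_, slope_ci = c(NA_real_, NA_real_),
         intercept = NA_real_, intercept_ci = c(NA_real_, NA_real_),
         converged = FALSE, flagged = TRUE, message = msg)
  }
  if (sd(lp) < .Machine$double.eps^0.5) {
    return(flagged_result("degenerate: predictions are constant"))
  }
  if (length(unique(y)) < 2) {
    return(flagged_result("degenerate: single-class outcome"))
  }
  X <- cbind(1, lp)
  fit <- logistic_fit(X, y)
  se <- sqrt(diag(fit$vcov))
  z <- qnorm(1 - (1 - conf_level) / 2)
  flagged <- !fit$converged || anyNA(se) || any(abs(fit$coef) > 20)
  msg <- if (!fit$converged) "did not converge (possible separation)" else
    if (any(abs(fit$coef) > 20)) "extreme coefficients (possible separation)"
    else ""
  list(slope = fit$coef[2], slope_ci = fit$coef[2] + c(-1, 1) * z * se[2],
       intercept = fit$coef[1],
       intercept_ci = fit$coef[1] + c(-1, 1) * z * se[1],
       converged = fit$converged, flagged = flagged, message = msg)
}

#' Confusion metrics at an explicit or Youden-optimal threshold
#'
#' Dichotomises scores at a threshold (score >= threshold predicts death)
#' and reports sensitivity, specificity, PPV and NPV. With
#' `threshold = "youden"` the threshold maximising sensitivity +
#' specificity - 1 over the observed score values is chosen; ties are broken
#' toward higher specificity (and then the higher threshold).
#'
#' @param scores Numeric scores, higher = predicted higher mortality.
#' @param outcomes Binary outcomes.
#' @param threshold `"youden"` or an explicit numeric cutoff.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `threshold`, `table` (2x2 counts: tp, fp, fn, tn).
#' @export
confusion_metrics <- function(scores, outcomes, threshold = "youden") {
  y <- check_binary_outcome(outcomes)
  stopifnot(length(scores) == length(y))
  metrics_at <- function(t) {
    pred <- scores >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         threshold = t, table = c(tp = tp, fp = fp, fn = fn, tn = tn))
  }
  if (identical(threshold, "youden")) {
    cand <- sort(unique(scores))
    res <- lapply(cand, metrics_at)
    youden <- vapply(res, function(r) r$sensitivity + r$specificity - 1,
                     numeric(1))
    spec <- vapply(res, `[[`, numeric(1), "specificity")
    best <- which(youden > max(youden) - 1e-12)
    best <- best[order(-spec[best], -cand[best])][1]
    res[[best]]
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    metrics_at(threshold)
  }
}

#' Stratum-level accuracy statistic
#'
#' Symmetric agreement between a stratum's nominal predicted mortality and
#' its observed mortality, `100 * min(p, o) / max(p, o)` (both in percent).
#' Equals 100 exactly when predicted and observed coincide, falls toward 0 as
#' they diverge in either direction; two zeros agree perfectly (100), one
#' zero is complete disagreement (0).
#'
#' @param predicted_pct Predicted mortality, percent, >= 0.
#' @param observed_pct Observed mortality, percent, >= 0.
#' @return Accuracy in percent (vectorised).
#' @examples
#' stratum_accuracy(12.1, 11.4)  # 94.2 to one decimal
#' @export
stratum_accuracy <- function(predicted_pct, observed_pct) {
  if (any(predicted_pct < 0, na.rm = TRUE) ||
      any(observed_pct < 0, na.rm = TRUE)) {
    stop("mortality percentages must be non-negative", call. = FALSE)
  }
  both <- cbind(predicted_pct, observed_pct)
  lo <- pmin(both[, 1], both[, 2])
  hi <- pmax(both[, 1], both[, 2])
  out <- ifelse(hi == 0, 100, 100 * lo / hi)
  as.numeric(out)
}

#' Predicted-versus-observed risk stratum table
#'
#' Cross-tabulates a model's risk strata against observed 1-year mortality:
#' per stratum, the number (and percent) of patients, the nominal predicted
#' mortality from the model configuration, the observed mortality, and the
#' stratum-accuracy statistic. Strata with no patients are retained with
#' `n = 0` and missing observed values, mirroring validation cohorts that
#' lack, e.g., a low-risk group.
#'
#' @param panel Score panel for one model (from [score_models] functions).
#' @param outcomes Binary 1-year death indicator, aligned with the panel
#'   rows.
#' @param spec Model specification or name (supplies strata and nominal
#'   predicted mortalities).
#' @param representative How interval-valued predicted mortalities are
#'   collapsed; see [stratum_predicted()].
#' @return Data frame with one row per stratum: `stratum`, `n`, `pct`,
#'   `predicted_pct`, `observed_pct`, `accuracy_pct`.
#' @export
stratum_table <- function(panel, outcomes, spec,
                          representative = c("upper", "lower", "mid")) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  representative <- match.arg(representative)
  y <- as.integer(as.logical(outcomes))
  stopifnot(nrow(panel) == length(y))
  pred <- stratum_predicted(spec, representative)
  labels <- names(pred)
  n_total <- nrow(panel)
  out <- lapply(labels, function(lb) {
    in_stratum <- panel$stratum == lb
    n <- sum(in_stratum)
    observed <- if (n > 0) 100 * sum(y[in_stratum]) / n else NA_real_
    acc <- if (n > 0 && !is.na(pred[[lb]])) {
      stratum_accuracy(pred[[lb]], observed)
    } else NA_real_
    data.frame(stratum = lb, n = n, pct = 100 * n / n_total,
               predicted_pct = pred[[lb]], observed_pct = observed,
               accuracy_pct = acc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hanley-McNeil minimum sample size for an AUC confidence interval
#'
#' Smallest total cohort size N such that a normal-approximation confidence
#' interval for an anticipated AUC has at most the requested half-width,
#' using the Hanley-McNeil standard error
#' `SE^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)] / (n1 n2)` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, `n1 = prevalence * N` events and
#' `n2 = (1-prevalence) * N` non-events.
#'
#' @param auc Anticipated AUC, in (0.5, 1).
#' @param ci_halfwidth Target confidence-interval half-width, in (0, 1).
#' @param prevalence Anticipated event fraction, in (0, 1).
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return Minimum total sample size (integer).
#' @examples
#' hanley_mcneil_n(0.70, 0.05, 0.134)  # about 1,079
#' @export
hanley_mcneil_n <- function(auc, ci_halfwidth, prevalence, z = 1.96) {
  if (!(auc > 0.5 && auc < 1)) stop("auc must lie in (0.5, 1)", call. = FALSE)
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (!(ci_halfwidth > 0 && ci_halfwidth < 1)) {
    stop("ci_halfwidth must lie in (0, 1)", call. = FALSE)
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- function(N) {
    n1 <- prevalence * N
    n2 <- (1 - prevalence) * N
    sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
            (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  }
  n_min <- ceiling(2 / min(prevalence, 1 - prevalence))
  if (z * se(1e9) > ci_halfwidth) {
    stop("infeasible: requested half-width unattainable", call. = FALSE)
  }
  lo <- n_min
  hi <- lo
  while (z * se(hi) > ci_halfwidth) hi <- hi * 2
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (z * se(mid) > ci_halfwidth) lo <- mid else hi <- mid
  }
  if (z * se(lo) <= ci_halfwidth) as.integer(lo) else as.integer(hi)
}
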