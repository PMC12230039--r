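# Right-censored survival machinery: Kaplan-Meier curves and two-group
# log-rank comparison, delegated to the survival package behind a small
# tabular surface. Time unit is months; the binary 1-year endpoint used
# elsewhere is death within 12.0 months (boundary inclusive).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function from right-censored
#' follow-up times. At tied times deaths are processed before censorings
#' (the standard convention). The returned curve starts at time 0 with
#' survival 1.
#'
#' @param followup_months Follow-up time in months, >= 0.
#' @param event_flags Binary event indicator (1/TRUE = death, else censored
#'   at the follow-up time).
#' @return Data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_estimate <- function(followup_months, event_flags) {
  time <- as.numeric(followup_months)
  event <- as.integer(as.logical(event_flags))
  stopifnot(length(time) == length(event))
  if (anyNA(time) || anyNA(event)) {
    stop("follow-up times and event flags must be complete", call. = FALSE)
  }
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    survival = c(1, fit$surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation (right-continuous) of a [km_estimate()] curve.
#'
#' @param curve A `km_curve`.
#' @param times Times (months) at which to evaluate survival.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  idx <- findInterval(times, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic (1 degree of freedom) comparing
#' right-censored survival between groups, e.g. male versus female 1-year
#' mortality.
#'
#' @param group_a,group_b Lists or data frames with elements/columns
#'   `time` (months) and `event` (1 = death).
#' @return List with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  ga <- as.data.frame(group_a); gb <- as.data.frame(group_b)
  for (g in list(ga, gb)) {
    if (!all(c("time", "event") %in% names(g))) {
      stop("each group needs 'time' and 'event'", call. = FALSE)
    }
  }
  if (nrow(ga) < 1 || nrow(gb) < 1) {
    stop("both groups must contain at least one subject", call. = FALSE)
  }
  time <- c(ga$time, gb$time)
  event <- as.integer(as.logical(c(ga$event, gb$event)))
  grp <- rep(c("a", "b"), c(nrow(ga), nrow(gb)))
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  if (sum(event) == 0) {
    # no events anywhere: no information, chi-square 0 by convention
    return(list(chi_square = 0, df = 1L, p = 1))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi_square = unname(fit$chisq), df = 1L,
       p = pchisq(unname(fit$chisq), df = 1, lower.tail = FALSE))
}

#' Export a Kaplan-Meier curve as TSV
#'
#' @param curve A `km_curve`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
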