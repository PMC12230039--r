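# Discrimination, calibration and classification statistics against
# exhaustive oracles, hand arithmetic and an independent implementation
# (pROC). The heavier seeded simulation suites (type-I error, CI coverage)
# live in test-acceptance.R; here the same properties are exercised at
# smaller sizes.

test_that("AUC equals the exhaustive concordant-pair oracle on small fixtures", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(12:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))          # both classes guaranteed
    s <- sample(round(rnorm(n), 1))              # ties likely
    expect_equal(roc_auc(s, y)$auc, auc_pair_oracle(s, y))
  }
})

test_that("AUC endpoints: perfect separation and all-tied scores", {
  y <- rep(c(1, 0), each = 6)
  expect_equal(roc_auc(c(rep(2, 6), rep(1, 6)), y)$auc, 1)
  expect_equal(roc_auc(rep(3, 12), y)$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  y <- rbinom(80, 1, 0.35)
  y[1:2] <- c(0, 1)
  s <- rnorm(80) + y
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(rank(s, ties.method = "average"), y)$auc, a0)
  expect_equal(roc_auc(-s, y)$auc, 1 - a0)
})

test_that("AUC and DeLong CI agree with pROC", {
  set.seed(31)
  y <- rbinom(120, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(120) + 1.2 * y
  ours <- roc_auc(s, y)
  ref <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-8)
})

test_that("DeLong self-comparison and orientation reversal behave as stated", {
  set.seed(41)
  y <- rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  self <- delong_test(s, s, y)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  rev <- delong_test(s, -s, y)
  expect_equal(rev$auc_b, 1 - rev$auc_a)
  # symmetry up to the sign of z
  b <- s + rnorm(60)
  ab <- delong_test(s, b, y)
  ba <- delong_test(b, s, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_error(delong_test(s[-1], s, y), "equal length")
})

test_that("DeLong p-value agrees with pROC's paired test", {
  set.seed(51)
  y <- rbinom(100, 1, 0.35); y[1:2] <- c(0, 1)
  a <- rnorm(100) + 1.0 * y
  b <- rnorm(100) + 0.4 * y
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow statistic is 0 with p = 1 when observed equals expected", {
  predicted <- rep(c(0.2, 0.5, 0.8), each = 10)
  outcomes <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(5, 5)),
                rep(c(1, 0), c(8, 2)))
  hl <- hosmer_lemeshow(predicted, outcomes)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p, 1)
  expect_equal(hl$groups_used, 3L)
  expect_equal(hl$df, 3L)                  # fixed predictions: g df
  expect_equal(hosmer_lemeshow(predicted, outcomes,
                               fit_adjusted = TRUE)$df, 1L)
})

test_that("Hosmer-Lemeshow matches hand chi-square arithmetic on a two-bin toy", {
  # bin A: 10 patients at p=0.2 (E1=2), 3 deaths; bin B: 10 at p=0.6 (E1=6),
  # 5 deaths. chi2 = 1/2 + 1/8 + 1/6 + 1/4 = 25/24
  predicted <- rep(c(0.2, 0.6), each = 10)
  outcomes <- c(rep(c(1, 0), c(3, 7)), rep(c(1, 0), c(5, 5)))
  hl <- hosmer_lemeshow(predicted, outcomes)
  expect_equal(hl$statistic, 25 / 24)
  expect_equal(hl$df, 2L)
  expect_equal(hl$p, pchisq(25 / 24, 2, lower.tail = FALSE))
  # the development-data reference leaves no degrees of freedom on 2 bins
  dev <- hosmer_lemeshow(predicted, outcomes, fit_adjusted = TRUE)
  expect_true(dev$degenerate)
  expect_true(is.na(dev$p))
  expect_error(hosmer_lemeshow(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("Hosmer-Lemeshow holds its type-I error at a reduced simulation size", {
  set.seed(61)
  predicted <- runif(400, 0.05, 0.5)
  rejections <- vapply(1:150, function(r) {
    y <- generate_calibrated_outcomes(predicted, seed = 1000 + r)
    hosmer_lemeshow(predicted, y)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.10)
})

test_that("calibration slope recovers truth and flags degeneracies", {
  set.seed(71)
  p_true <- runif(4000, 0.05, 0.6)
  y <- generate_calibrated_outcomes(p_true, seed = 72)
  cal <- calibration_slope(p_true, y)
  expect_false(cal$flagged)
  expect_lt(abs(cal$slope - 1), 0.15)
  expect_true(cal$slope_ci[1] <= cal$slope && cal$slope <= cal$slope_ci[2])

  # predictions logit-shrunk by 0.5 relative to the data-generating risk
  shrunk <- plogis(0.5 * qlogis(p_true))
  cal2 <- calibration_slope(shrunk, y)
  expect_lt(abs(cal2$slope - 2), 0.3)

  flat <- calibration_slope(rep(0.3, 100), rbinom(100, 1, 0.3))
  expect_true(flat$flagged)
  expect_match(flat$message, "constant")
})

test_that("calibration slope matches glm on the same clipped logit", {
  set.seed(81)
  p <- runif(300, 0.1, 0.9)
  y <- rbinom(300, 1, p)
  ours <- calibration_slope(p, y)
  ref <- glm(y ~ qlogis(p), family = binomial())
  expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
})

test_that("confusion metrics reproduce hand arithmetic and edge thresholds", {
  # 44 true positives, 16 false negatives, 121 true negatives, 26 false
  # positives at threshold 1
  scores <- c(rep(1, 44), rep(0, 16), rep(1, 26), rep(0, 121))
  outcomes <- c(rep(1, 60), rep(0, 147))
  cm <- confusion_metrics(scores, outcomes, threshold = 1)
  expect_equal(round(cm$sensitivity, 3), 0.733)
  expect_equal(round(cm$specificity, 3), 0.823)
  expect_equal(cm$table[["tp"]], 44)

  # Youden rule lands on the same cutoff here
  expect_equal(confusion_metrics(scores, outcomes)$threshold, 1)

  perfect <- confusion_metrics(c(5, 5, 1, 1), c(1, 1, 0, 0), threshold = 5)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  low <- confusion_metrics(c(5, 5, 1, 1), c(1, 1, 0, 0), threshold = 0)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
})

test_that("Youden ties break toward higher specificity", {
  # thresholds 2 and 4 both have Youden index 0.5; 4 has higher specificity
  scores <- c(1, 2, 3, 4)
  outcomes <- c(0, 1, 0, 1)
  cm <- confusion_metrics(scores, outcomes)
  expect_equal(cm$threshold, 4)
  expect_equal(cm$specificity, 1)
})

test_that("stratum accuracy reproduces its defining properties", {
  expect_equal(stratum_accuracy(5, 5), 100)
  expect_equal(stratum_accuracy(0, 0), 100)
  expect_equal(stratum_accuracy(0, 7), 0)
  expect_equal(stratum_accuracy(7, 0), 0)
  set.seed(91)
  p <- runif(50, 0, 60); o <- runif(50, 0, 60)
  expect_equal(stratum_accuracy(p, o), stratum_accuracy(o, p))
  expect_true(all(stratum_accuracy(p, o) <= 100))
  expect_true(all((stratum_accuracy(p, o) == 100) == (p == o)))
  expect_error(stratum_accuracy(-1, 5), "non-negative")
})

test_that("stratum table reports observed mortality and empty strata", {
  # every NHFS high-risk patient dies
  df <- make_patients(
    make_patient(age = 90L, sex = "male", hemoglobin = 9,
                 cognitive_impairment = TRUE, residence = "long_term_care",
                 n_comorbidities = 3L, dead_1y = TRUE, followup_months = 3),
    make_patient(age = 88L, sex = "male", hemoglobin = 9,
                 n_comorbidities = 4L, malignancy = "other", dead_1y = TRUE,
                 followup_months = 8),
    make_patient(age = 83L, n_comorbidities = 2L),
    make_patient(age = 60L))
  panel <- score_nhfs(df)
  st <- stratum_table(panel, df$dead_1y, "nhfs")
  expect_equal(st$observed_pct[st$stratum == "high"], 100)
  expect_equal(st$n, c(1L, 1L, 2L))

  # observed mortality 4/35 = 11.4%
  df35 <- do.call(rbind, lapply(1:35, function(i)
    make_patient(patient_id = paste0("Q", i), dead_1y = i <= 4,
                 followup_months = if (i <= 4) 6 else 24)))
  panel35 <- score_nhfs(df35)
  st35 <- stratum_table(panel35, df35$dead_1y, "nhfs")
  expect_equal(round(st35$observed_pct[st35$stratum == "low"], 1), 11.4)
  # empty strata stay in the table with n = 0 and render as "None"
  expect_equal(st35$n[st35$stratum == "high"], 0L)
  expect_true(is.na(st35$observed_pct[st35$stratum == "high"]))
})

test_that("Hanley-McNeil sample size reproduces the planning estimate", {
  n <- hanley_mcneil_n(auc = 0.70, ci_halfwidth = 0.05, prevalence = 0.134)
  expect_gte(n, 1070)
  expect_lte(n, 1085)
  # SE ~ 1/sqrt(N): halving the half-width roughly quadruples N
  n2 <- hanley_mcneil_n(0.70, 0.025, 0.134)
  expect_gt(n2 / n, 3.8)
  expect_lt(n2 / n, 4.2)
  # class imbalance inflates the requirement; the optimum is interior
  # (slightly above 0.5 because the Hanley-McNeil variance components for
  # cases and controls are asymmetric)
  grid <- seq(0.1, 0.9, by = 0.1)
  ns <- vapply(grid, function(pr) hanley_mcneil_n(0.70, 0.05, pr), integer(1))
  opt <- grid[which.min(ns)]
  expect_gte(opt, 0.4)
  expect_lte(opt, 0.7)
  expect_gt(ns[grid == 0.1], min(ns))
  expect_gt(ns[grid == 0.9], min(ns))
  expect_error(hanley_mcneil_n(0.4, 0.05, 0.2), "auc")
})
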