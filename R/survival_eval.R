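# Outcome derivation and the survival evaluation suite: classification
# metrics, ROC/AUC, Kaplan-Meier curves, log-rank test, Cox PH hazard
# ratio, Harrell's concordance index, and split-sensitivity analysis.

#' Build a survival record table
#'
#' @param patient_id Character vector.
#' @param time_days Positive times to event/censoring in days.
#' @param event 1 = death observed, 0 = censored.
#' @return Data.frame of class `survival_records`.
#' @export
survival_records <- function(patient_id, time_days, event) {
  assert_that(all(time_days > 0), "time_days must be positive")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1")
  structure(data.frame(patient_id = as.character(patient_id),
                       time_days = as.numeric(time_days),
                       event = as.integer(event),
                       stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

#' Derive binary one-year survival labels
#'
#' Label 1 if the patient is known to survive past the horizon (time >=
#' horizon, event or censored), label 0 if death is observed before the
#' horizon. Patients censored before the horizon have an unknowable
#' status and are excluded from classification (but retained for the
#' time-to-event analyses).
#'
#' @param records A [survival_records()] data.frame.
#' @param horizon_days Classification horizon, default 365.
#' @return List with `labels` (named 0/1 vector over labelable
#'   patients) and `excluded` (patient_ids censored before the horizon).
#' @export
derive_labels <- function(records, horizon_days = 365) {
  assert_that(horizon_days > 0, "horizon must be positive")
  lab1 <- records$time_days >= horizon_days
  lab0 <- records$event == 1 & records$time_days < horizon_days
  excluded <- records$patient_id[!lab1 & !lab0]
  keep <- lab1 | lab0
  list(labels = stats::setNames(as.integer(lab1[keep]),
                                records$patient_id[keep]),
       excluded = excluded)
}

#' Confusion-matrix classification metrics
#'
#' Positive class = predicted/actual survival beyond the horizon.
#'
#' @param pred Binary predictions.
#' @param labels Binary truth, aligned.
#' @return Named numeric vector: accuracy, sensitivity, specificity,
#'   precision (each NA-free; a ratio with empty denominator is NA).
#' @export
classification_metrics <- function(pred, labels) {
  assert_that(length(pred) == length(labels) && length(pred) > 0,
              "pred and labels must be aligned and non-empty")
  pred <- as.integer(pred)
  labels <- as.integer(labels)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  c(accuracy = (tp + tn) / length(pred),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: the probability that a random
#' positive outscores a random negative, ties counting one half. Equals
#' the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary truth.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps the standard product-limit estimator; the median is the first
#' time at which the survival curve drops to 0.5 or below, reported as
#' `NA` (not reached) when the curve never does.
#'
#' @param records A [survival_records()] data.frame.
#' @return A `km_curve`: `time` (ascending), `surv`, `n_risk`,
#'   `n_event`, `median_days`.
#' @export
km_estimate <- function(records) {
  assert_that(nrow(records) > 0, "no records")
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ 1, data = records)
  surv <- fit$surv
  med <- if (any(surv <= 0.5)) fit$time[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = fit$time, surv = surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median_days = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, median %s days\n",
              length(x$time),
              if (is.na(x$median_days)) "not reached" else
                format(x$median_days)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param group_a,group_b [survival_records()] data.frames.
#' @return List `chi2`, `p` (chi-square with 1 df).
#' @export
logrank_test <- function(group_a, group_b) {
  assert_that(nrow(group_a) > 0 && nrow(group_b) > 0,
              "both groups must be non-empty")
  assert_that(sum(group_a$event) + sum(group_b$event) >= 1,
              "log-rank test undefined with zero events")
  df <- rbind(data.frame(time = group_a$time_days, event = group_a$event,
                         g = 0L),
              data.frame(time = group_b$time_days, event = group_b$event,
                         g = 1L))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Hazard ratio from a single-binary-covariate Cox model
#'
#' Cox proportional-hazards partial likelihood with Breslow handling of
#' tied event times; HR = exp(beta) for group 1 vs group 0 with a Wald
#' 95% confidence interval. A monotone likelihood (all events on one
#' side) or non-convergence is flagged and reported with an infinite
#' interval rather than a spurious finite one.
#'
#' @param records A [survival_records()] data.frame.
#' @param group Binary vector aligned with `records`.
#' @return List `hr`, `ci_lo`, `ci_hi`, `beta`, `se`, `flagged`.
#' @export
cox_hr <- function(records, group) {
  group <- as.integer(group)
  assert_that(length(group) == nrow(records), "group not aligned")
  assert_that(length(unique(group)) == 2, "both group levels required")
  assert_that(sum(records$event) >= 1, "need at least one event")
  df <- data.frame(time = records$time_days, event = records$event,
                   g = group)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, data = df,
                    ties = "breslow",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 50) flagged <- TRUE
  if (flagged && (!is.finite(se) || se > 50)) {
    return(list(hr = exp(beta), ci_lo = 0, ci_hi = Inf, beta = beta,
                se = se, flagged = TRUE))
  }
  list(hr = exp(beta), ci_lo = exp(beta - 1.96 * se),
       ci_hi = exp(beta + 1.96 * se), beta = beta, se = se,
       flagged = flagged)
}

#' Harrell's concordance index
#'
#' Over comparable pairs (the earlier time is an observed event and the
#' times differ), the pair is concordant when the patient with the
#' earlier event has the higher risk score; score ties count one half.
#' Orientation: `risk` is a risk score (higher = earlier expected
#' death); classifier survival scores must be passed as `1 - score`.
#'
#' @param risk Numeric risk scores.
#' @param records A [survival_records()] data.frame aligned with `risk`.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, records) {
  assert_that(length(risk) == nrow(records), "risk not aligned")
  t <- records$time_days
  e <- records$event
  n <- length(t)
  # comparable: t_i < t_j with event_i observed
  conc <- 0
  comp <- 0
  for (i in which(e == 1)) {
    j <- which(t > t[i])
    if (length(j) == 0) next
    comp <- comp + length(j)
    conc <- conc + sum(risk[i] > risk[j]) + 0.5 * sum(risk[i] == risk[j])
  }
  assert_that(comp > 0, "no comparable pair")
  conc / comp
}

#' Assemble the evaluation report for one model on one test set
#'
#' Computes the full suite on a held-out set: confusion-matrix metrics
#' and AUC over patients with a knowable one-year status, then
#' concordance, Kaplan-Meier stratification by predicted group,
#' log-rank test, Cox hazard ratio (predicted short-survivors vs
#' long-survivors), and the separation in median survival between the
#' predicted groups.
#'
#' @param scores Survival scores in `[0, 1]` (higher = predicted to
#'   survive past the horizon), aligned with `records`.
#' @param pred Binary predictions at the model threshold.
#' @param records [survival_records()] for the same patients.
#' @param horizon_days Label horizon.
#' @return An `eval_report` list.
#' @export
eval_report <- function(scores, pred, records, horizon_days = 365) {
  lab <- derive_labels(records, horizon_days)
  known <- records$patient_id %in% names(lab$labels)
  labels <- lab$labels[records$patient_id[known]]
  metrics <- classification_metrics(pred[known], labels)
  auc <- if (length(unique(labels)) == 2) {
    roc_auc(scores[known], labels)
  } else NA_real_
  cidx <- concordance_index(1 - scores, records)
  g_pos <- records[pred == 1, , drop = FALSE]
  g_neg <- records[pred == 0, , drop = FALSE]
  km_pos <- if (nrow(g_pos) > 0) km_estimate(g_pos) else NULL
  km_neg <- if (nrow(g_neg) > 0) km_estimate(g_neg) else NULL
  two_groups <- nrow(g_pos) > 0 && nrow(g_neg) > 0
  lr <- if (two_groups && sum(records$event) >= 1) {
    logrank_test(g_neg, g_pos)
  } else list(chi2 = NA_real_, p = NA_real_)
  hr <- if (two_groups) {
    # hazard of predicted short-survivors relative to predicted
    # long-survivors (HR > 1 expected for an informative model)
    tryCatch(cox_hr(records, as.integer(pred == 0)),
             error = function(e) list(hr = NA_real_, ci_lo = NA_real_,
                                      ci_hi = NA_real_, flagged = TRUE))
  } else list(hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
              flagged = TRUE)
  sep <- if (two_groups && !is.na(km_pos$median_days) &&
             !is.na(km_neg$median_days)) {
    abs(km_pos$median_days - km_neg$median_days)
  } else NA_real_
  structure(list(metrics = metrics, auc = auc, c_index = cidx,
                 hr = hr$hr, hr_ci = c(hr$ci_lo, hr$ci_hi),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 km_by_group = list(model_positive = km_pos,
                                    model_negative = km_neg),
                 median_separation_days = sep,
                 n = nrow(records), n_labelable = sum(known)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d (labelable %d)\n  accuracy %.3f  sens %.3f  spec %.3f  prec %.3f\n  AUC %.3f  c-index %.3f  HR %.2f [%.2f, %.2f]  log-rank p %.3g\n  median separation %s days\n",
    x$n, x$n_labelable, x$metrics["accuracy"], x$metrics["sensitivity"],
    x$metrics["specificity"], x$metrics["precision"], x$auc, x$c_index,
    x$hr, x$hr_ci[1], x$hr_ci[2], x$logrank_p,
    if (is.na(x$median_separation_days)) "NA" else
      format(x$median_separation_days)))
  invisible(x)
}
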