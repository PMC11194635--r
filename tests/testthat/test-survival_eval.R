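toy_records <- function(time, event) {
  survival_records(sprintf("p%02d", seq_along(time)), time, event)
}

test_that("one-year labels split into survivors, deaths, and unknowables", {
  rec <- toy_records(c(400, 200, 200, 365), c(0, 1, 0, 0))
  lab <- derive_labels(rec)
  expect_equal(unname(lab$labels[c("p01", "p02")]), c(1, 0))
  expect_identical(lab$excluded, "p03")
  expect_equal(unname(lab$labels["p04"]), 1)  # exactly at the horizon
})

test_that("classification metrics match hand arithmetic", {
  m <- classification_metrics(rep(c(1, 0), c(5, 5)),
                              rep(c(1, 0), c(5, 5)))
  expect_equal(unname(m["accuracy"]), 1)
  # TP=3, FN=1, TN=2, FP=2
  pred <- c(1, 1, 1, 0, 0, 0, 1, 1)
  lab <-  c(1, 1, 1, 1, 0, 0, 0, 0)
  m2 <- classification_metrics(pred, lab)
  expect_equal(unname(m2), c(0.625, 0.75, 0.5, 0.6),
               tolerance = 1e-12)
  m3 <- classification_metrics(rep(1, 8), lab)
  expect_equal(unname(m3["sensitivity"]), 1)
  expect_equal(unname(m3["specificity"]), 0)
})

test_that("AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  for (rep in 1:20) {
    set.seed(rep)
    n <- sample(5:30, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    brute <- 0
    pos <- which(lb == 1); neg <- which(lb == 0)
    for (i in pos) for (j in neg) {
      brute <- brute + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    }
    expect_equal(roc_auc(sc, lb), brute / (length(pos) * length(neg)))
  }
  skip_if_not_installed("pROC")
  set.seed(99)
  sc <- runif(50); lb <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("Kaplan-Meier estimate matches the hand-computed toy", {
  km <- km_estimate(toy_records(c(1, 2, 3, 4), c(1, 1, 0, 1)))
  expect_equal(km$surv[km$time == 1], 0.75)
  expect_equal(km$surv[km$time == 2], 0.50)
  expect_equal(km$surv[km$time == 4], 0)
  expect_equal(km$median_days, 2)
  # all censored: flat curve, median not reached
  km2 <- km_estimate(toy_records(c(5, 6, 7), c(0, 0, 0)))
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median_days))
  # no censoring: complement of the ECDF at event times
  tm <- c(2, 5, 9, 14, 20)
  km3 <- km_estimate(toy_records(tm, rep(1, 5)))
  expect_equal(km3$surv, 1 - stats::ecdf(tm)(km3$time))
})

test_that("log-rank test is symmetric and detects separation", {
  a <- toy_records(c(10, 20, 30), c(1, 1, 1))
  lr0 <- logrank_test(a, a)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  b <- toy_records(c(200, 300, 400), c(1, 1, 1))
  lr <- logrank_test(a, b)
  expect_lt(lr$p, 0.05)
  expect_equal(logrank_test(b, a)$chi2, lr$chi2)
  expect_error(logrank_test(toy_records(5, 0), toy_records(6, 0)),
               "zero events")
})

test_that("Cox beta matches grid-search maximization of the partial likelihood", {
  set.seed(21)
  n <- 40
  g <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, rate = 0.01 * exp(0.8 * g))
  e <- as.integer(t < quantile(t, 0.8))
  t <- pmin(t, quantile(t, 0.8))
  rec <- toy_records(t, e)
  fit <- cox_hr(rec, g)
  # independent oracle: Breslow partial log-likelihood on a beta grid
  pll <- function(beta) {
    s <- 0
    for (i in which(e == 1)) {
      rs <- which(t >= t[i])
      s <- s + beta * g[i] - log(sum(exp(beta * g[rs])))
    }
    s
  }
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, pll, numeric(1))
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$beta))
  expect_lte(fit$ci_lo, fit$hr)
  expect_gte(fit$ci_hi, fit$hr)
  # flipping the group inverts the hazard ratio
  flip <- cox_hr(rec, 1 - g)
  expect_equal(flip$hr, 1 / fit$hr, tolerance = 1e-8)
})

test_that("Cox HR is 1 for identical groups and flagged when monotone", {
  rec <- toy_records(rep(c(5, 10, 15), 2), rep(1, 6))
  fit <- cox_hr(rec, rep(c(0, 1), 3))
  expect_equal(fit$hr, 1, tolerance = 1e-8)
  # complete separation: all events in one group -> infinite CI
  rec2 <- toy_records(c(1, 2, 3, 100, 100, 100), c(1, 1, 1, 0, 0, 0))
  fit2 <- suppressWarnings(cox_hr(rec2, c(1, 1, 1, 0, 0, 0)))
  expect_true(fit2$flagged)
  expect_equal(fit2$ci_hi, Inf)
})

test_that("Cox recovers a known hazard ratio under censoring", {
  set.seed(33)
  cover <- 0
  hrs <- numeric(100)
  for (r in 1:100) {
    n <- 500
    g <- rbinom(n, 1, 0.5)
    t <- rweibull(n, 1.2, 400) * exp(-log(2) * g / 1.2)  # true HR 2
    cens <- runif(n, 0, 1200)
    rec <- toy_records(pmax(pmin(t, cens), 0.01), as.integer(t <= cens))
    fit <- cox_hr(rec, g)
    hrs[r] <- fit$hr
    if (fit$ci_lo <= 2 && fit$ci_hi >= 2) cover <- cover + 1
  }
  expect_gt(mean(hrs), 1.6)
  expect_lt(mean(hrs), 2.5)
  expect_gte(cover, 90)
})

test_that("concordance index equals exhaustive pair enumeration", {
  rec <- toy_records(c(1, 2, 3), c(1, 1, 1))
  expect_equal(concordance_index(c(3, 2, 1), rec), 1)
  expect_equal(concordance_index(c(1, 1, 1), rec), 0.5)
  for (rep in 1:20) {
    set.seed(rep + 200)
    n <- sample(8:30, 1)
    t <- sample(1:15, n, replace = TRUE)  # force tied times
    e <- rbinom(n, 1, 0.7)
    risk <- sample(seq(0, 1, 0.2), n, replace = TRUE)  # tied scores
    rec <- toy_records(t, e)
    conc <- 0; comp <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      if (e[i] == 1 && t[i] < t[j]) {
        comp <- comp + 1
        conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
    if (comp == 0) next
    expect_equal(concordance_index(risk, rec), conc / comp)
  }
})

test_that("concordance orientation agrees with the survival package", {
  set.seed(44)
  n <- 60
  t <- round(rexp(n, 0.01), 4)  # continuous: no tied times
  e <- rbinom(n, 1, 0.7)
  risk <- rnorm(n)
  rec <- toy_records(t, e)
  ref <- survival::concordance(survival::Surv(t, e) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(concordance_index(risk, rec), ref, tolerance = 1e-12)
})

test_that("c-index hits its anchors: oracle 1, anti-oracle 0, noise 0.5", {
  set.seed(55)
  n <- 500
  t <- rexp(n, 0.01)
  rec <- toy_records(t, rep(1, n))
  expect_equal(concordance_index(-t, rec), 1)
  expect_equal(concordance_index(t, rec), 0)
  expect_equal(concordance_index(rnorm(n), rec), 0.5, tolerance = 0.05)
})

test_that("evaluation report wires metrics and median separation together", {
  set.seed(66)
  n <- 120
  eta <- rnorm(n)
  t <- rweibull(n, 1.2, 450) * exp(-eta / 1.2)
  rec <- toy_records(pmax(t, 1), rep(1, n))
  scores <- 1 - stats::pnorm(eta)   # higher score = predicted survivor
  pred <- as.integer(scores >= 0.5)
  rep_ <- eval_report(scores, pred, rec)
  expect_s3_class(rep_, "eval_report")
  expect_true(all(rep_$metrics >= 0 & rep_$metrics <= 1, na.rm = TRUE))
  expect_gt(rep_$c_index, 0.6)
  expect_lt(rep_$logrank_p, 0.05)
  expect_gt(rep_$hr, 1)             # predicted short-survivors die faster
  km <- rep_$km_by_group
  expect_equal(rep_$median_separation_days,
               abs(km$model_positive$median_days -
                     km$model_negative$median_days))
})
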