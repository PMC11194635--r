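strata_table <- function(n, strata = NULL) {
  df <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  if (!is.null(strata)) df$grp <- strata
  df
}

test_that("stratified splitting apportions 80:20 with an inner 64:16", {
  sp <- split_cohort(strata_table(100), split_spec(seed = 1))
  expect_length(sp$test, 20)
  expect_length(sp$train, 64)
  expect_length(sp$val, 16)
  # two strata of 50 each contribute 40 train(+val) / 10 test apiece
  tab <- strata_table(100, rep(c("a", "b"), each = 50))
  sp2 <- split_cohort(tab, split_spec(strata_keys = "grp", seed = 2))
  for (g in c("a", "b")) {
    ids <- tab$patient_id[tab$grp == g]
    expect_length(intersect(sp2$test, ids), 10)
    expect_length(intersect(c(sp2$train, sp2$val), ids), 40)
  }
})

test_that("splits are disjoint, exhaustive, and seed-reproducible", {
  for (seed in 1:5) {
    tab <- strata_table(83, sample(c("x", "y", "z"), 83, replace = TRUE))
    spec <- split_spec(strata_keys = "grp", seed = seed)
    sp <- split_cohort(tab, spec)
    all_ids <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_ids), sort(tab$patient_id))
    expect_equal(anyDuplicated(all_ids), 0)
    expect_identical(split_cohort(tab, spec), sp)
  }
})

test_that("undersized strata go wholly to training with a warning", {
  tab <- strata_table(22, rep(c("big", "tiny"), c(20, 2)))
  expect_warning(sp <- split_cohort(tab, split_spec(strata_keys = "grp",
                                                    seed = 3)),
                 "tiny")
  tiny_ids <- tab$patient_id[tab$grp == "tiny"]
  expect_true(all(tiny_ids %in% sp$train))
})

sep_data <- function(n, seed = 1, informative = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 10), n,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- as.integer(x[, informative] > 0)
    list(table = cbind(data.frame(patient_id = as.character(seq_len(n))),
                       as.data.frame(x)),
         labels = y)
  })
}

small_grid <- list(max_depth = 2, eta = 0.3, subsample = 1,
                   nrounds = 60, early_stopping_rounds = 15)

test_that("a separable problem is fit to resubstitution accuracy 1", {
  d <- sep_data(200)
  tr <- d$table[1:150, ]; va <- d$table[151:200, ]
  m <- train_classifier(tr, d$labels[1:150], va, d$labels[151:200],
                        hyperparams = small_grid, seed = 7)
  pr <- predict(m, tr)
  expect_equal(mean(pr$pred == d$labels[1:150]), 1)
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
  expect_s3_class(m, "wl_model")
  expect_true(m$threshold > 0 && m$threshold < 1)
})

test_that("training is deterministic down to the scores", {
  d <- sep_data(120, seed = 5)
  tr <- d$table[1:90, ]; va <- d$table[91:120, ]
  m1 <- train_classifier(tr, d$labels[1:90], va, d$labels[91:120],
                         hyperparams = small_grid, seed = 11)
  m2 <- train_classifier(tr, d$labels[1:90], va, d$labels[91:120],
                         hyperparams = small_grid, seed = 11)
  expect_identical(predict(m1, d$table)$scores,
                   predict(m2, d$table)$scores)
})

test_that("permuted labels give chance-level held-out AUC", {
  d <- sep_data(500, seed = 9)
  y <- withr::with_seed(10, sample(d$labels))   # break the association
  tr <- d$table[1:300, ]; va <- d$table[301:380, ]
  te <- d$table[381:500, ]
  m <- train_classifier(tr, y[1:300], va, y[301:380],
                        hyperparams = small_grid, seed = 12)
  auc <- roc_auc(predict(m, te)$scores, y[381:500])
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("Youden threshold matches an exhaustive scan and its tie rule", {
  # perfectly separated: any threshold in (0.2, 0.8) attains J = 1
  th <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  pred <- c(0.1, 0.2, 0.8, 0.9) >= th
  expect_equal(pred, c(FALSE, FALSE, TRUE, TRUE))
  # degenerate: identical scores
  expect_warning(thd <- select_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)),
                 "degenerate")
  expect_equal(thd, 0.4)
  # random instances vs brute-force scan over all candidate cuts
  for (rep in 1:10) {
    set.seed(rep + 300)
    sc <- round(runif(40), 2)
    lb <- rbinom(40, 1, 0.5)
    if (length(unique(lb)) < 2) next
    th <- select_threshold(sc, lb)
    jfun <- function(t) {
      mean(sc[lb == 1] >= t) + mean(sc[lb == 0] < t) - 1
    }
    jall <- vapply(sort(unique(sc)), jfun, numeric(1))
    expect_equal(jfun(th), max(jall), tolerance = 1e-12)
    # tie rule: no lower candidate attains the same J
    lower <- sort(unique(sc))[sort(unique(sc)) < th]
    if (length(lower) > 0) {
      expect_true(all(vapply(lower, jfun, numeric(1)) < jfun(th) - 1e-12))
    }
  }
})

test_that("prediction applies the >= threshold rule and ignores extras", {
  d <- sep_data(100, seed = 13)
  tr <- d$table[1:70, ]; va <- d$table[71:100, ]
  m <- train_classifier(tr, d$labels[1:70], va, d$labels[71:100],
                        hyperparams = small_grid, seed = 14)
  m$threshold <- 0.5
  pr <- predict(m, d$table)
  expect_equal(unname(pr$pred), as.integer(pr$scores >= 0.5))
  # extra irrelevant columns leave scores untouched
  aug <- cbind(d$table, junk = rnorm(100))
  expect_identical(predict(m, aug)$scores, pr$scores)
  # permuting rows permutes but does not change scores
  perm <- withr::with_seed(15, sample(100))
  expect_equal(unname(predict(m, d$table[perm, ])$scores),
               unname(pr$scores[perm]))
  # missing model features are reported by name
  expect_error(predict(m, d$table[, 1:5]), "f5")
})

test_that("permutation importance ranks the informative feature first", {
  d <- sep_data(300, seed = 16, informative = 3)
  tr <- d$table[1:200, ]; va <- d$table[201:250, ]
  te <- d$table[251:300, ]
  m <- train_classifier(tr, d$labels[1:200], va, d$labels[201:250],
                        hyperparams = small_grid, seed = 17)
  imp <- feature_attribution(m, te, d$labels[251:300], n_repeats = 5,
                             seed = 18)
  expect_equal(imp$feature[1], "f3")
  expect_gt(imp$importance[1], 0.1)
  # an unused feature has (near) zero importance
  expect_lt(max(abs(imp$importance[imp$feature != "f3"])), 0.1)
})
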