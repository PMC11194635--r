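# Stratified cohort splitting, gradient-boosted one-year-survival
# classification, ROC-based threshold selection, prediction, and
# permutation feature attribution. The three model variants (clinical
# C, radiomic R, combined C+R) share this code path and differ only in
# which feature columns they see.

#' Cohort split specification
#'
#' Patients are split within strata (e.g. biomarker status x study)
#' into training and test sets, and the training set is further divided
#' into an inner training and validation set for model tuning and
#' threshold selection.
#'
#' @param fractions Length-2 `(train, test)` fractions summing to 1.
#' @param strata_keys Column names defining the strata.
#' @param inner_val_fraction Fraction of the training set held out as
#'   the inner validation set.
#' @param seed Integer seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(fractions = c(0.8, 0.2),
                       strata_keys = character(0),
                       inner_val_fraction = 0.2, seed = 1L) {
  assert_that(length(fractions) == 2 && all(fractions > 0) &&
                abs(sum(fractions) - 1) < 1e-8,
              "fractions must be two positive values summing to 1")
  assert_that(inner_val_fraction > 0 && inner_val_fraction < 1,
              "inner_val_fraction must be in (0, 1)")
  structure(list(fractions = fractions, strata_keys = strata_keys,
                 inner_val_fraction = inner_val_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of n into parts ~ fractions.
partition_counts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Within each stratum, patient ids are shuffled under the seed and
#' apportioned to train and test by largest-remainder rounding of the
#' fractions; the training part is then split again into inner train
#' and validation the same way. Strata with fewer than 3 patients are
#' assigned wholly to training with a warning. The three partitions are
#' disjoint and exhaustive.
#'
#' @param table Data.frame with `patient_id` and the strata columns.
#' @param spec A [split_spec()].
#' @return List of character vectors `train`, `val`, `test` (`train`
#'   excludes `val`).
#' @export
split_cohort <- function(table, spec = split_spec()) {
  assert_that(all(spec$strata_keys %in% names(table)),
              "strata column(s) missing from table")
  ids <- as.character(table$patient_id)
  strata <- if (length(spec$strata_keys) == 0) {
    rep("all", nrow(table))
  } else {
    do.call(paste, c(lapply(spec$strata_keys, function(k) table[[k]]),
                     sep = "|"))
  }
  train <- val <- test <- character(0)
  for (s in sort(unique(strata))) {
    sid <- ids[strata == s]
    sid <- with_seed(derive_seed(spec$seed, "split", s), sample(sid))
    if (length(sid) < 3) {
      warnf("stratum '%s' has %d patient(s); assigned wholly to training",
            s, length(sid))
      train <- c(train, sid)
      next
    }
    cnt <- partition_counts(length(sid), spec$fractions)
    tr <- sid[seq_len(cnt[1])]
    test <- c(test, sid[-seq_len(cnt[1])])
    # inner validation split of the training part
    cnt2 <- partition_counts(length(tr),
                             c(1 - spec$inner_val_fraction,
                               spec$inner_val_fraction))
    train <- c(train, tr[seq_len(cnt2[1])])
    if (cnt2[2] > 0) val <- c(val, tr[-seq_len(cnt2[1])])
  }
  list(train = train, val = val, test = test)
}

default_hyperparam_grid <- function() {
  list(max_depth = c(2, 3, 4), eta = c(0.05, 0.1),
       subsample = c(0.8, 1.0), nrounds = 500, early_stopping_rounds = 25)
}

xgb_matrix <- function(table, feature_names, labels = NULL) {
  X <- as.matrix(table[, feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  if (is.null(labels)) xgboost::xgb.DMatrix(X, nthread = 1)
  else xgboost::xgb.DMatrix(X, label = as.numeric(labels), nthread = 1)
}

#' Train the gradient-boosted survival classifier
#'
#' Tunes an XGBoost binary classifier over a small hyperparameter grid
#' by validation log-loss with early stopping, selects the decision
#' threshold from the validation ROC (Youden's J) using the tuned
#' model, then refits with the chosen settings and stopping round on
#' the combined training + validation data (so the threshold is fixed
#' before the validation labels enter the fit). Deterministic given the
#' seed: single-threaded histogram trees.
#'
#' @param train Data.frame with `patient_id` and feature columns (the
#'   selected features).
#' @param train_labels Binary labels aligned with `train`.
#' @param val,val_labels Inner validation set, same layout.
#' @param hyperparams Optional grid overriding
#'   `default_hyperparam_grid()`; scalars fix a value.
#' @param variant Model variant tag (`"C"`, `"R"`, `"C+R"`).
#' @param seed Integer seed.
#' @return A `wl_model`: `booster`, `threshold`, `feature_names`,
#'   `variant`, `hyperparams`, `config_fingerprint`, `val_score`.
#' @export
train_classifier <- function(train, train_labels, val, val_labels,
                             hyperparams = NULL, variant = "C+R",
                             seed = 1L) {
  assert_that(length(unique(train_labels)) == 2,
              "training labels must contain both classes")
  feature_names <- setdiff(names(train), "patient_id")
  grid <- utils::modifyList(default_hyperparam_grid(),
                            hyperparams %||% list())
  combos <- expand.grid(max_depth = grid$max_depth, eta = grid$eta,
                        subsample = grid$subsample,
                        KEEP.OUT.ATTRS = FALSE)
  dtrain <- xgb_matrix(train, feature_names, train_labels)
  dval <- xgb_matrix(val, feature_names, val_labels)
  # tuning and early stopping monitor validation log-loss: on the small
  # inner validation sets typical of survival cohorts the AUC is a step
  # function with high variance, which makes stopping degenerate, while
  # the log-loss is smooth (and remains defined for a one-class set)
  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    params <- list(objective = "binary:logistic",
                   eval_metric = "logloss",
                   tree_method = "hist", nthread = 1,
                   seed = derive_seed(seed, "xgb", ci),
                   max_depth = combos$max_depth[ci], eta = combos$eta[ci],
                   subsample = combos$subsample[ci])
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = grid$nrounds,
                              evals = list(val = dval),
                              early_stopping_rounds =
                                grid$early_stopping_rounds,
                              verbose = 0)
    score <- as.numeric(xgboost::xgb.attr(fit, "best_score"))
    it <- as.integer(xgboost::xgb.attr(fit, "best_iteration"))
    if (is.null(best) || score < best$score - 1e-12) {
      best <- list(score = score, iter = max(it, 1L), params = params,
                   fit = fit)
    }
  }
  # threshold from the validation ROC of the tuned (train-only) model
  val_scores <- predict(best$fit, dval,
                        iterationrange = c(1, best$iter + 1))
  threshold <- if (length(unique(val_labels)) == 2) {
    select_threshold(val_scores, val_labels)
  } else 0.5
  # refit on train + validation with the frozen settings
  both <- rbind(train[, c("patient_id", feature_names)],
                val[, c("patient_id", feature_names)])
  dboth <- xgb_matrix(both, feature_names,
                      c(train_labels, val_labels))
  booster <- xgboost::xgb.train(params = best$params, data = dboth,
                                nrounds = best$iter, verbose = 0)
  fingerprint <- object_md5(list(best$params, best$iter, feature_names,
                                 variant))
  structure(list(booster = booster, threshold = threshold,
                 feature_names = feature_names, variant = variant,
                 hyperparams = best$params, best_iter = best$iter,
                 val_metric = "logloss", val_score = best$score,
                 config_fingerprint = fingerprint,
                 seed = as.integer(seed)),
            class = "wl_model")
}

#' Youden-optimal decision threshold from a validation ROC
#'
#' Scans the observed scores as candidate thresholds (prediction rule:
#' `score >= threshold`) and returns the one maximizing Youden's J =
#' sensitivity + specificity - 1; ties are broken toward higher
#' sensitivity (the lower threshold). When every score is identical the
#' ROC is degenerate and the common score is returned with a warning.
#'
#' @param scores Numeric validation scores.
#' @param labels Binary validation labels.
#' @return The selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) == 2,
              "both classes required for threshold selection")
  cand <- sort(unique(scores))
  if (length(cand) == 1) {
    warnf("degenerate ROC: all scores identical; returning midpoint")
    return(cand)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, numeric(1))
  # ties toward higher sensitivity = lower threshold
  cand[which(j >= max(j) - 1e-12)[1]]
}

#' Predict one-year survival from a trained model
#'
#' Scores are survival probabilities in `[0, 1]` (higher = predicted to
#' survive past the horizon); the binary call is `score >= threshold`.
#' Extra columns in `table` are ignored; missing model features raise
#' an error naming them.
#'
#' @param object A `wl_model`.
#' @param table Data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return List with `scores` and `pred`, named by `patient_id` when
#'   present.
#' @export
predict.wl_model <- function(object, table, ...) {
  missing_cols <- setdiff(object$feature_names, names(table))
  assert_that(length(missing_cols) == 0,
              "missing feature column(s): %s",
              paste(missing_cols, collapse = ", "))
  d <- xgb_matrix(table, object$feature_names)
  scores <- predict(object$booster, d)
  nm <- if ("patient_id" %in% names(table)) {
    as.character(table$patient_id)
  } else NULL
  list(scores = stats::setNames(as.numeric(scores), nm),
       pred = stats::setNames(as.integer(scores >= object$threshold), nm))
}

#' Permutation feature importance
#'
#' Model-agnostic attribution: each feature column is shuffled
#' `n_repeats` times and the mean drop in AUC relative to the intact
#' table is reported, ranked descending. Features the trees never use
#' score 0 (up to permutation noise).
#'
#' @param model A `wl_model`.
#' @param table Data.frame with the model features.
#' @param labels Binary labels aligned with `table`.
#' @param n_repeats Shuffles per feature.
#' @param seed Integer seed.
#' @return Data.frame `feature`, `importance`, sorted descending.
#' @export
feature_attribution <- function(model, table, labels, n_repeats = 10,
                                seed = 1L) {
  assert_that(nrow(table) == length(labels), "labels not aligned")
  base_auc <- roc_auc(predict(model, table)$scores, labels)
  imp <- vapply(model$feature_names, function(fn) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      tb <- table
      tb[[fn]] <- with_seed(derive_seed(seed, "perm", fn, r),
                            sample(tb[[fn]]))
      base_auc - roc_auc(predict(model, tb)$scores, labels)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}
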