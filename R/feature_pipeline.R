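# Patient-level feature assembly: cross-patch aggregation, clinical
# encoding, and bootstrapped correlation + mutual-information feature
# selection.

AGG_STATS <- c("mean", "median", "min", "max", "sum", "mad", "skew",
               "kurtosis")

# Population skew / excess kurtosis; 0 on zero-variance samples so
# aggregated tables stay finite.
sample_skew <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 > 0) mean((x - mean(x))^3) / m2^1.5 else 0
}
sample_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 > 0) mean((x - mean(x))^4) / m2^2 - 3 else 0
}

#' Aggregate per-patch features to one patient row
#'
#' Each per-patch feature is summarized across the patches by eight
#' statistics -- mean, median, minimum, maximum, sum, mean absolute
#' deviation (about the mean), skew, and excess kurtosis -- giving a
#' holistic whole-lung description and a fixed-width row regardless of
#' patch count. Output width is exactly 8x the per-patch feature count;
#' patch order does not matter.
#'
#' @param patch_features List of named numeric vectors (one per patch)
#'   with identical name sets, or a patches x features numeric matrix.
#' @return Named numeric vector with names `<feature>.<stat>`.
#' @export
aggregate_patient <- function(patch_features) {
  if (is.list(patch_features)) {
    assert_that(length(patch_features) >= 1, "no patches to aggregate")
    nms <- names(patch_features[[1]])
    ok <- vapply(patch_features, function(v) identical(names(v), nms),
                 logical(1))
    assert_that(all(ok), "patches have mismatched feature name sets")
    X <- do.call(rbind, patch_features)
  } else {
    X <- as.matrix(patch_features)
    nms <- colnames(X)
  }
  stats_fun <- list(mean = colMeans(X),
                    median = apply(X, 2, median),
                    min = apply(X, 2, min),
                    max = apply(X, 2, max),
                    sum = colSums(X),
                    mad = apply(X, 2, function(x) mean(abs(x - mean(x)))),
                    skew = apply(X, 2, sample_skew),
                    kurtosis = apply(X, 2, sample_kurtosis))
  out <- unlist(lapply(AGG_STATS, function(s) {
    stats::setNames(stats_fun[[s]], paste(nms, s, sep = "."))
  }))
  out
}

#' Clinical covariate schema
#'
#' Declares which clinical columns are categorical (to be binary
#' encoded) and which are numeric (passed through); remaining columns
#' except the identifier are rejected so misconfiguration surfaces
#' immediately.
#'
#' @param categorical,numeric Character vectors of column names.
#' @param id_col Patient identifier column.
#' @return A `clinical_schema` list.
#' @export
clinical_schema <- function(categorical, numeric, id_col = "patient_id") {
  structure(list(categorical = categorical, numeric = numeric,
                 id_col = id_col), class = "clinical_schema")
}

#' Binary-encode clinical covariates
#'
#' Categorical covariates (e.g. sex, smoking history, ECOG performance
#' status, treatment combination) are encoded into binary indicator
#' columns, one per non-reference level (reference = first sorted
#' level); numeric covariates pass through. Patients with any missing
#' value among the schema columns are flagged for exclusion rather than
#' imputed, matching the cohort-building rule that incomplete clinical
#' records leave the analysis set.
#'
#' @param raw Data.frame of raw clinical records.
#' @param schema A [clinical_schema()].
#' @return List with `table` (encoded data.frame indexed by
#'   `patient_id`, complete rows only) and `excluded` (patient_ids
#'   flagged for missing values).
#' @export
encode_clinical <- function(raw, schema) {
  assert_that(inherits(schema, "clinical_schema"), "schema required")
  need <- c(schema$id_col, schema$categorical, schema$numeric)
  missing_cols <- setdiff(need, names(raw))
  assert_that(length(missing_cols) == 0, "unknown/missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  ids <- as.character(raw[[schema$id_col]])
  assert_that(!anyDuplicated(ids), "duplicate patient_id in clinical data")
  use <- raw[, setdiff(need, schema$id_col), drop = FALSE]
  incomplete <- !stats::complete.cases(use)
  excluded <- ids[incomplete]
  keep <- raw[!incomplete, , drop = FALSE]
  out <- data.frame(patient_id = ids[!incomplete],
                    stringsAsFactors = FALSE)
  for (col in schema$categorical) {
    lv <- sort(unique(as.character(keep[[col]])))
    for (l in lv[-1]) {
      out[[paste(col, l, sep = "_")]] <-
        as.numeric(as.character(keep[[col]]) == l)
    }
    if (length(lv) == 1) {
      out[[paste(col, lv, sep = "_")]] <- rep(0, nrow(keep))
    }
  }
  for (col in schema$numeric) out[[col]] <- as.numeric(keep[[col]])
  list(table = out, excluded = excluded)
}

#' Feature selection configuration
#'
#' Houses the selection thresholds: pairs with absolute Spearman
#' correlation above `spearman_threshold` are reduced to one member;
#' the `top_k` features by mutual information with the one-year label
#' are taken per bootstrap; the procedure runs on `n_bootstraps`
#' resamples of the training set and features selected at least
#' `min_votes` times make the final set.
#'
#' @param spearman_threshold Absolute Spearman cutoff in (0, 1].
#' @param top_k Features kept per bootstrap.
#' @param n_bootstraps Number of bootstrap resamples.
#' @param min_votes Minimum vote count for final selection.
#' @param n_bins Bins for the mutual-information estimator.
#' @param seed Integer seed.
#' @return A `selection_config` list.
#' @export
selection_config <- function(spearman_threshold = 0.9, top_k = 20,
                             n_bootstraps = 5, min_votes = 2,
                             n_bins = 10, seed = 1L) {
  assert_that(spearman_threshold > 0 && spearman_threshold <= 1,
              "spearman_threshold must be in (0, 1]")
  assert_that(is_count(top_k) && is_count(n_bootstraps),
              "top_k and n_bootstraps must be positive integers")
  assert_that(is_count(min_votes) && min_votes <= n_bootstraps,
              "need 1 <= min_votes <= n_bootstraps")
  structure(list(spearman_threshold = spearman_threshold,
                 top_k = as.integer(top_k),
                 n_bootstraps = as.integer(n_bootstraps),
                 min_votes = as.integer(min_votes),
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "selection_config")
}

# Feature columns of a patient table (everything except patient_id).
feature_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), "patient_id"), drop = FALSE])
}

#' Drop one member of every highly correlated feature pair
#'
#' Greedy elimination: columns are visited in priority order (highest
#' first) and kept only if their absolute Spearman correlation with
#' every already-kept column is at or below the threshold, so the
#' surviving set provably contains no violating pair. By default the
#' priority is the column order; the selection procedure passes
#' per-feature mutual information so the more informative member of a
#' pair survives. Zero-variance columns (Spearman undefined) are treated
#' as uncorrelated.
#'
#' @param table Data.frame with `patient_id` plus numeric feature
#'   columns (>= 2 rows).
#' @param threshold Absolute Spearman cutoff (pairs strictly above are
#'   reduced).
#' @param priority Optional named numeric vector scoring each feature;
#'   higher is kept preferentially, ties broken lexicographically.
#' @return The table restricted to the retained columns.
#' @export
spearman_dedup <- function(table, threshold = 0.9, priority = NULL) {
  X <- feature_matrix(table)
  assert_that(nrow(X) >= 2, "need >= 2 rows to estimate correlations")
  cols <- colnames(X)
  if (is.null(priority)) {
    priority <- stats::setNames(rev(seq_along(cols)), cols)
  }
  ord <- order(-priority[cols], cols)
  rho <- suppressWarnings(cor(X, method = "spearman"))
  rho[is.na(rho)] <- 0
  kept <- character(0)
  for (cn in cols[ord]) {
    if (length(kept) == 0 ||
        all(abs(rho[cn, kept]) <= threshold)) {
      kept <- c(kept, cn)
    }
  }
  table[, c("patient_id", cols[cols %in% kept]), drop = FALSE]
}

#' Plug-in mutual information between a feature and a binary label
#'
#' A continuous feature is discretized into `n_bins` equal-frequency
#' bins (rank-based, so the value is invariant under strictly monotone
#' transforms); a feature with at most `n_bins` distinct values (e.g. a
#' binary indicator) is used as categorical directly, since
#' equal-frequency breaks are degenerate there. The plug-in mutual
#' information with the label is returned in bits; non-negative by
#' construction.
#'
#' @param feature Numeric vector.
#' @param labels Binary vector (both classes present).
#' @param n_bins Number of quantile bins (>= 2).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(feature, labels, n_bins = 10) {
  assert_that(length(feature) == length(labels), "length mismatch")
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) == 2,
              "labels must contain both classes")
  assert_that(is_count(n_bins) && n_bins >= 2, "n_bins must be >= 2")
  if (length(unique(feature)) <= 1) {
    return(0)  # constant feature carries no information
  }
  if (length(unique(feature)) <= n_bins) {
    bins <- factor(feature)
  } else {
    br <- unique(quantile(feature,
                          probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE, type = 7))
    bins <- cut(feature, breaks = br, include.lowest = TRUE)
  }
  tab <- table(bins, labels)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  expected <- outer(px, py)
  max(0, sum(pxy[nz] * log2(pxy[nz] / expected[nz])))
}

#' Bootstrapped correlation + mutual-information feature selection
#'
#' On each of `cfg$n_bootstraps` resamples (rows drawn with replacement)
#' the correlated-pair reduction runs first, the surviving features are
#' ranked by mutual information with the label, and the top
#' `cfg$top_k` are recorded. Features recorded at least `cfg$min_votes`
#' times across the bootstraps make the final set. Resamples whose
#' labels collapse to one class are redrawn (at most 100 times). Fully
#' deterministic given `cfg$seed`.
#'
#' @param table Data.frame with `patient_id` plus feature columns.
#' @param labels Binary vector aligned with the rows of `table`.
#' @param cfg A [selection_config()].
#' @return A `selection_result`: `selected` (character), `votes` (named
#'   integer), `per_bootstrap` (list of character vectors), `seed`.
#' @export
bootstrap_select <- function(table, labels, cfg = selection_config()) {
  labels <- as.integer(labels)
  assert_that(nrow(table) == length(labels),
              "table and labels are not aligned")
  assert_that(length(unique(labels)) == 2,
              "labels must contain both classes")
  cols <- setdiff(names(table), "patient_id")
  per_bootstrap <- vector("list", cfg$n_bootstraps)
  for (b in seq_len(cfg$n_bootstraps)) {
    idx <- NULL
    for (try in seq_len(100)) {
      idx <- with_seed(derive_seed(cfg$seed, "bootstrap", b, try), {
        sample.int(nrow(table), replace = TRUE)
      })
      if (length(unique(labels[idx])) == 2) break
      idx <- NULL
    }
    assert_that(!is.null(idx),
                "bootstrap %d: could not draw a two-class resample", b)
    tb <- table[idx, , drop = FALSE]
    lb <- labels[idx]
    mi <- vapply(cols, function(cn) {
      mutual_information(tb[[cn]], lb, cfg$n_bins)
    }, numeric(1))
    dd <- spearman_dedup(tb, cfg$spearman_threshold, priority = mi)
    surv <- setdiff(names(dd), "patient_id")
    ranked <- surv[order(-mi[surv], surv)]
    per_bootstrap[[b]] <- utils::head(ranked, cfg$top_k)
  }
  votes <- table(factor(unlist(per_bootstrap), levels = cols))
  votes <- stats::setNames(as.integer(votes), names(votes))
  selected <- names(votes)[votes >= cfg$min_votes]
  structure(list(selected = selected, votes = votes,
                 per_bootstrap = per_bootstrap, seed = cfg$seed),
            class = "selection_result")
}

#' Assemble a patient feature table from per-patch features
#'
#' @param patch_table Long data.frame (`patient_id`, `patch_index`,
#'   feature columns) as produced by the extraction stage.
#' @return Wide data.frame, one row per patient, aggregated columns.
#' @export
aggregate_cohort <- function(patch_table) {
  feat_cols <- setdiff(names(patch_table), c("patient_id", "patch_index"))
  ids <- unique(patch_table$patient_id)
  rows <- lapply(ids, function(pid) {
    X <- as.matrix(patch_table[patch_table$patient_id == pid, feat_cols,
                               drop = FALSE])
    aggregate_patient(X)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), out)
}
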