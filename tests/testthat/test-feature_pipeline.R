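test_that("patient aggregation emits the eight summary statistics", {
  # constant feature across 80 patches
  pf <- lapply(1:80, function(i) c(f1 = 2.5))
  a <- aggregate_patient(pf)
  expect_length(a, 8)
  expect_equal(unname(a[c("f1.mean", "f1.median", "f1.min", "f1.max")]),
               rep(2.5, 4))
  expect_equal(unname(a["f1.sum"]), 200)
  expect_equal(unname(a[c("f1.mad", "f1.skew", "f1.kurtosis")]),
               c(0, 0, 0))
  # mean absolute deviation about the mean: hand value 2.4
  b <- aggregate_patient(lapply(c(1, 2, 3, 4, 10), function(v) c(x = v)))
  expect_equal(unname(b["x.mad"]), 2.4)
  # symmetric sample has zero skew
  s <- aggregate_patient(lapply(c(-1, 0, 1), function(v) c(x = v)))
  expect_equal(unname(s["x.skew"]), 0)
})

test_that("aggregation is 8x-wide and invariant to patch order", {
  pf <- withr::with_seed(1, lapply(1:20, function(i) {
    stats::setNames(rnorm(5), paste0("f", 1:5))
  }))
  a <- aggregate_patient(pf)
  expect_length(a, 40)
  perm <- withr::with_seed(2, sample(20))
  expect_equal(aggregate_patient(pf[perm]), a)
  # mismatched feature sets are rejected
  bad <- pf
  names(bad[[3]])[2] <- "other"
  expect_error(aggregate_patient(bad), "mismatch")
})

test_that("clinical encoding produces binary indicators and flags missing", {
  raw <- data.frame(patient_id = c("a", "b", "c", "d"),
                    sex = c("M", "F", "M", "F"),
                    ecog = c("0", "1", "1", "0"),
                    albumin = c(40, 38, NA, 44),
                    stringsAsFactors = FALSE)
  schema <- clinical_schema(categorical = c("sex", "ecog"),
                            numeric = "albumin")
  enc <- encode_clinical(raw, schema)
  expect_identical(enc$excluded, "c")
  expect_identical(names(enc$table),
                   c("patient_id", "sex_M", "ecog_1", "albumin"))
  expect_equal(enc$table$sex_M, c(1, 0, 0))
  expect_equal(enc$table$ecog_1, c(0, 1, 0))
  expect_error(
    encode_clinical(raw, clinical_schema("smoking", "albumin")),
    "smoking")
})

test_that("spearman dedup removes exactly the violating pairs", {
  x <- withr::with_seed(3, rnorm(60))
  tab <- data.frame(patient_id = as.character(1:60),
                    a = x, b = x, c = -x,
                    d = withr::with_seed(4, rnorm(60)))
  out <- spearman_dedup(tab, threshold = 0.9)
  feats <- setdiff(names(out), "patient_id")
  # a, b identical and c = -a (|rho| = 1): one survivor of {a, b, c}
  expect_length(intersect(feats, c("a", "b", "c")), 1)
  expect_true("d" %in% feats)
  # priority keeps the higher-scoring member
  out2 <- spearman_dedup(tab, threshold = 0.9,
                         priority = c(a = 0, b = 5, c = 1, d = 2))
  expect_true("b" %in% names(out2))
  expect_false(any(c("a", "c") %in% names(out2)))
})

test_that("independent columns survive dedup and the audit is clean", {
  n <- 200
  tab <- withr::with_seed(5, {
    cbind(data.frame(patient_id = as.character(1:n)),
          as.data.frame(matrix(rnorm(n * 40), n,
                               dimnames = list(NULL, paste0("v", 1:40)))))
  })
  out <- spearman_dedup(tab, threshold = 0.9)
  expect_equal(ncol(out), ncol(tab))  # all retained
  rho <- cor(as.matrix(out[, -1]), method = "spearman")
  diag(rho) <- 0
  expect_lte(max(abs(rho)), 0.9)
})

test_that("mutual information behaves like an information measure", {
  y <- rep(c(0, 1), each = 500)
  # feature identical to a balanced label: H(Y) = 1 bit
  expect_equal(mutual_information(as.numeric(y), y), 1)
  # independence: plug-in MI stays near zero at n = 2000
  x <- withr::with_seed(6, rnorm(2000))
  yy <- rep(c(0, 1), 1000)
  expect_lte(mutual_information(x, yy), 0.02)
  # rank invariance under strictly monotone transforms
  x2 <- withr::with_seed(7, rnorm(300))
  y2 <- withr::with_seed(8, rbinom(300, 1, 0.5))
  expect_equal(mutual_information(x2, y2), mutual_information(exp(x2), y2))
  # binary features are treated as categories, not quantile bins
  xb <- rep(c(0, 1), each = 100)
  expect_equal(mutual_information(xb, rep(c(0, 1), each = 100)), 1)
  expect_error(mutual_information(x2, rep(1, 300)), "both classes")
})

test_that("bootstrap selection votes deterministically and finds signal", {
  n <- 300
  y <- withr::with_seed(9, rbinom(n, 1, 0.5))
  tab <- withr::with_seed(10, {
    cbind(data.frame(patient_id = as.character(1:n)),
          signal = y + rnorm(n, sd = 0.5),
          as.data.frame(matrix(rnorm(n * 50), n,
                               dimnames = list(NULL, paste0("n", 1:50)))))
  })
  cfg <- selection_config(top_k = 5, seed = 11)
  res <- bootstrap_select(tab, y, cfg)
  expect_s3_class(res, "selection_result")
  expect_true("signal" %in% res$selected)
  expect_equal(unname(res$votes["signal"]), 5)
  expect_length(res$per_bootstrap, 5)
  expect_true(all(lengths(res$per_bootstrap) <= 5))
  expect_true(all(res$votes <= cfg$n_bootstraps))
  expect_true(all(res$selected %in% names(tab)))
  # identical seed reproduces the full result
  expect_identical(bootstrap_select(tab, y, cfg), res)
  # single-feature table: that feature collects every vote
  solo <- bootstrap_select(tab[, c("patient_id", "signal")], y, cfg)
  expect_identical(solo$selected, "signal")
  expect_equal(unname(solo$votes["signal"]), 5)
})

test_that("aggregate_cohort pivots long patch features to patient rows", {
  long <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                     patch_index = rep(1:3, 2),
                     f1 = c(1, 2, 3, 4, 5, 6), f2 = 0)
  wide <- aggregate_cohort(long)
  expect_equal(nrow(wide), 2)
  expect_equal(ncol(wide), 1 + 16)
  expect_equal(wide$f1.mean, c(2, 5))
  expect_equal(wide$f1.sum, c(6, 15))
})
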