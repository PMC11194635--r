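# End-to-end orchestration: simulate/load -> QC -> harmonize -> sample
# -> extract -> aggregate -> encode -> split -> select -> train ->
# evaluate, under a single nested configuration with one master seed
# fanned out to per-stage, per-patient sub-seeds.

pipeline_sections <- c("seed", "variants", "sim", "qc", "harmonize",
                       "sampling", "quantization", "features",
                       "selection", "split", "model", "eval")

#' Default pipeline configuration
#'
#' A nested list with one section per stage. Every value can be
#' overridden through [pipeline_config()]; unknown keys are rejected.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    variants = c("C", "R", "C+R"),
    sim = list(n_patients = 40, grid = c(96, 96, 48),
               spacing_mm = c(0.8, 0.8, 4.0),
               spacing_sd_mm = c(0.08, 0.08, 0.8),
               beta_radiomic = 0.8,
               beta_clinical = default_beta_clinical(),
               baseline_median_days = 332,
               censor_horizon_days = 1826,
               weibull_shape = 1.2, missing_rate = 0.03),
    qc = list(max_in_plane_mm = 1.0, max_slice_mm = 10.0),
    harmonize = list(clip_low = -120, clip_high = 300),
    sampling = list(n_patches = 80, patch_edge_mm = 10 * 5^(1 / 3),
                    center_domain = "auto"),
    quantization = list(mode = "fixed_bin_width", bin_width = 25,
                        n_bins = 16, anchor = -120),
    features = list(spec = default_feature_spec(), gldm_alpha = 0),
    selection = list(spearman_threshold = 0.9, top_k = 20,
                     n_bootstraps = 5, min_votes = 2, n_bins = 10),
    split = list(fractions = c(0.8, 0.2),
                 strata_keys = c("pd_l1", "study"),
                 inner_val_fraction = 0.2),
    model = list(max_depth = c(2, 3, 4), eta = c(0.05, 0.1),
                 subsample = c(0.8, 1.0), nrounds = 500,
                 early_stopping_rounds = 25),
    eval = list(horizon_days = 365)
  )
}

merge_config <- function(base, override, path = "config") {
  check_known_keys(override, names(base), path)
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste(path, k, sep = "$"))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Build and validate a pipeline configuration
#'
#' Accepts a nested list of overrides or a YAML file path; values merge
#' into [default_pipeline_config()]. Validation is strict: unknown keys
#' anywhere in the tree are fatal, so silent misconfiguration cannot
#' slip through.
#'
#' @param x NULL (defaults), a nested list, or a YAML file path.
#' @param seed Optional master seed overriding the config value.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL, seed = NULL) {
  cfg <- default_pipeline_config()
  if (is.character(x) && length(x) == 1) {
    x <- yaml::read_yaml(x)
  }
  if (!is.null(x)) cfg <- merge_config(cfg, x)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  assert_that(all(cfg$variants %in% c("C", "R", "C+R")),
              "variants must be a subset of C, R, C+R")
  structure(cfg, class = "pipeline_config")
}

sim_config_from <- function(cfg) {
  s <- cfg$sim
  sim_config(n_patients = s$n_patients, grid = s$grid,
             spacing_mm = s$spacing_mm, spacing_sd_mm = s$spacing_sd_mm,
             beta_radiomic = s$beta_radiomic,
             beta_clinical = unlist(s$beta_clinical),
             baseline_median_days = s$baseline_median_days,
             censor_horizon_days = s$censor_horizon_days,
             weibull_shape = s$weibull_shape,
             missing_rate = s$missing_rate, seed = cfg$seed)
}

#' Extract per-patch radiomic features for a cohort
#'
#' For every QC-eligible patient: clip to the harmonization window,
#' crop to the lung bounding box, sample patches, and extract the
#' configured features. Per-patient failures are logged and skipped;
#' the run aborts if more than 10% of patients fail.
#'
#' @param cohort A `sim_cohort` (volumes are regenerated on demand) or
#'   a directory produced by [simulate_cohort()]'s `out_dir`.
#' @param cfg A [pipeline_config()].
#' @param progress Print per-patient progress.
#' @return List: `features` (long data.frame: `patient_id`,
#'   `patch_index`, one column per feature), `qc` (QC decision table),
#'   `failed` (patient ids that errored).
#' @export
run_extract <- function(cohort, cfg = pipeline_config(),
                        progress = FALSE) {
  from_dir <- is.character(cohort)
  if (from_dir) {
    img_dir <- file.path(cohort, "images")
    ct_files <- sort(list.files(img_dir, pattern = "_ct\\.nii(\\.gz)?$",
                                full.names = TRUE))
    ids <- sub("_ct\\.nii(\\.gz)?$", "", basename(ct_files))
  } else {
    ids <- cohort$truth$patient_id
  }
  get_patient <- function(pid) {
    if (from_dir) {
      vol <- read_volume(file.path(img_dir, paste0(pid, "_ct.nii.gz")),
                         patient_id = pid)
      roi <- read_mask(file.path(img_dir, paste0(pid, "_mask.nii.gz")))
      list(vol = vol, roi = roi)
    } else {
      cohort_volume(cohort, pid)
    }
  }
  # QC on acquisition geometry
  meta <- do.call(rbind, lapply(ids, function(pid) {
    sp <- if (from_dir) {
      abs(RNifti::pixdim(RNifti::readNifti(
        file.path(img_dir, paste0(pid, "_ct.nii.gz")))))
    } else {
      cohort$truth$spacing[match(pid, cohort$truth$patient_id), ]
    }
    data.frame(patient_id = pid, in_plane_mm = max(sp[1:2]),
               slice_mm = sp[3], stringsAsFactors = FALSE)
  }))
  qc <- qc_filter(meta, max_in_plane_mm = cfg$qc$max_in_plane_mm,
                  max_slice_mm = cfg$qc$max_slice_mm)
  eligible <- qc$patient_id[qc$eligible]
  qcfg <- quantization_config(mode = cfg$quantization$mode,
                              bin_width = cfg$quantization$bin_width,
                              n_bins = cfg$quantization$n_bins,
                              anchor = cfg$quantization$anchor,
                              clip_range = c(cfg$harmonize$clip_low,
                                             cfg$harmonize$clip_high))
  failed <- character(0)
  rows <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    pid <- eligible[i]
    rows[[i]] <- tryCatch({
      pr <- get_patient(pid)
      vol <- clip_hu(pr$vol, cfg$harmonize$clip_low,
                     cfg$harmonize$clip_high)
      cr <- crop_to_roi(vol, pr$roi)
      scfg <- sampling_config(n_patches = cfg$sampling$n_patches,
                              patch_edge_mm = cfg$sampling$patch_edge_mm,
                              center_domain = cfg$sampling$center_domain,
                              seed = derive_seed(cfg$seed, "sampling",
                                                 pid))
      patches <- sample_patches(cr$vol, cr$roi, scfg)
      fmat <- t(vapply(patches, function(p) {
        extract_patch_features(p, qcfg, cfg$features$spec,
                               cfg$features$gldm_alpha)
      }, numeric(length(cfg$features$spec))))
      if (progress) message("extracted ", pid)
      cbind(data.frame(patient_id = pid,
                       patch_index = seq_along(patches),
                       stringsAsFactors = FALSE),
            as.data.frame(fmat))
    }, error = function(e) {
      warnf("extraction failed for %s: %s", pid, conditionMessage(e))
      failed <<- c(failed, pid)
      NULL
    })
  }
  assert_that(length(failed) <= 0.1 * length(eligible),
              "extraction failed for %d of %d patients", length(failed),
              length(eligible))
  list(features = do.call(rbind, rows), qc = qc, failed = failed)
}

#' Assemble the modeling dataset for a cohort
#'
#' Runs extraction + aggregation for the radiomic table, encodes the
#' clinical table, and intersects the patients passing QC, having
#' complete clinical records, and having survival follow-up. Column
#' provenance (`radiomic` / `clinical`) is recorded for the variant
#' filters.
#'
#' @param cohort A `sim_cohort` or cohort directory.
#' @param cfg A [pipeline_config()].
#' @return List: `radiomic`, `clinical` (feature tables), `strata`
#'   (patient_id + strata columns), `records` ([survival_records()]),
#'   `provenance`, `qc`, `excluded`.
#' @export
assemble_dataset <- function(cohort, cfg = pipeline_config()) {
  ex <- run_extract(cohort, cfg)
  radiomic <- aggregate_cohort(ex$features)
  if (is.character(cohort)) {
    clin_raw <- read.csv(file.path(cohort, "clinical.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(ecog = "character"))
    surv_raw <- read.csv(file.path(cohort, "survival.csv"),
                         stringsAsFactors = FALSE)
    records <- survival_records(surv_raw$patient_id, surv_raw$time_days,
                                surv_raw$event)
  } else {
    clin_raw <- cohort$clinical
    records <- cohort$survival
  }
  enc <- encode_clinical(clin_raw, sim_clinical_schema())
  ids <- Reduce(intersect, list(radiomic$patient_id,
                                enc$table$patient_id,
                                records$patient_id))
  strata <- clin_raw[match(ids, clin_raw$patient_id),
                     c("patient_id", "study", "pd_l1")]
  list(radiomic = radiomic[match(ids, radiomic$patient_id), ,
                           drop = FALSE],
       clinical = enc$table[match(ids, enc$table$patient_id), ,
                            drop = FALSE],
       strata = strata,
       records = records[match(ids, records$patient_id), , drop = FALSE],
       provenance = c(
         stats::setNames(rep("radiomic",
                             ncol(radiomic) - 1),
                         setdiff(names(radiomic), "patient_id")),
         stats::setNames(rep("clinical", ncol(enc$table) - 1),
                         setdiff(names(enc$table), "patient_id"))),
       qc = ex$qc,
       excluded = list(qc = ex$qc$patient_id[!ex$qc$eligible],
                       clinical_missing = enc$excluded,
                       extraction_failed = ex$failed))
}

variant_table <- function(dataset, variant) {
  switch(variant,
         "C" = dataset$clinical,
         "R" = dataset$radiomic,
         "C+R" = merge(dataset$clinical, dataset$radiomic,
                       by = "patient_id", sort = FALSE),
         stopf("unknown variant %s", variant))
}

# Drop zero-variance columns (no ranking information, Spearman
# undefined) before selection.
drop_constant_cols <- function(table) {
  keep <- vapply(setdiff(names(table), "patient_id"), function(cn) {
    length(unique(table[[cn]])) > 1
  }, logical(1))
  table[, c("patient_id", names(keep)[keep]), drop = FALSE]
}

#' Select features, train and evaluate one model variant
#'
#' Feature selection runs independently per provenance (clinical and
#' radiomic) on the training patients (inner train + validation) with
#' a knowable one-year label, the C+R variant consuming the union of
#' the two selections. The classifier is tuned on the inner split,
#' thresholded on the validation ROC, refit on the full training set,
#' and evaluated on the held-out test set.
#'
#' @param dataset From [assemble_dataset()].
#' @param variant `"C"`, `"R"` or `"C+R"`.
#' @param split List `train`, `val`, `test` of patient ids.
#' @param cfg A [pipeline_config()].
#' @param seed Seed for selection and training.
#' @return List: `model`, `selection` (per provenance), `report`
#'   ([eval_report()]), `test_scores`, `test_pred`.
#' @export
run_variant <- function(dataset, variant, split,
                        cfg = pipeline_config(),
                        seed = cfg$seed) {
  lab <- derive_labels(dataset$records, cfg$eval$horizon_days)
  provs <- switch(variant, "C" = "clinical", "R" = "radiomic",
                  "C+R" = c("clinical", "radiomic"))
  sel_ids <- c(split$train, split$val)
  sel_ids <- sel_ids[sel_ids %in% names(lab$labels)]
  selections <- list()
  selected <- character(0)
  for (pv in provs) {
    tab <- if (pv == "clinical") dataset$clinical else dataset$radiomic
    tab <- drop_constant_cols(
      tab[match(sel_ids, tab$patient_id), , drop = FALSE])
    scfg <- selection_config(
      spearman_threshold = cfg$selection$spearman_threshold,
      top_k = cfg$selection$top_k,
      n_bootstraps = cfg$selection$n_bootstraps,
      min_votes = cfg$selection$min_votes,
      n_bins = cfg$selection$n_bins,
      seed = derive_seed(seed, "select", variant, pv))
    res <- bootstrap_select(tab, lab$labels[sel_ids], scfg)
    selections[[pv]] <- res
    selected <- c(selected, res$selected)
  }
  assert_that(length(selected) > 0,
              "no feature selected for variant %s", variant)
  full <- variant_table(dataset, variant)
  full <- full[, c("patient_id", selected), drop = FALSE]
  pick <- function(ids, labeled = TRUE) {
    if (labeled) ids <- ids[ids %in% names(lab$labels)]
    full[match(ids, full$patient_id), , drop = FALSE]
  }
  tr <- pick(split$train)
  va <- pick(split$val)
  model <- train_classifier(tr, lab$labels[tr$patient_id],
                            va, lab$labels[va$patient_id],
                            hyperparams = cfg$model, variant = variant,
                            seed = derive_seed(seed, "train", variant))
  te_all <- pick(split$test, labeled = FALSE)
  pr <- predict(model, te_all)
  rec_te <- dataset$records[match(split$test,
                                  dataset$records$patient_id), ,
                            drop = FALSE]
  report <- eval_report(pr$scores, pr$pred, rec_te,
                        cfg$eval$horizon_days)
  list(model = model, selection = selections, report = report,
       test_scores = pr$scores, test_pred = pr$pred)
}

report_to_list <- function(r) {
  list(accuracy = unname(r$metrics["accuracy"]),
       sensitivity = unname(r$metrics["sensitivity"]),
       specificity = unname(r$metrics["specificity"]),
       precision = unname(r$metrics["precision"]),
       auc = r$auc, c_index = r$c_index, hr = r$hr,
       hr_ci = r$hr_ci, logrank_p = r$logrank_p,
       median_separation_days = r$median_separation_days,
       n = r$n, n_labelable = r$n_labelable)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a cohort (unless one is supplied), assembles the dataset,
#' draws one stratified split shared by all requested variants, and
#' selects/trains/evaluates each variant. When `out_dir` is given,
#' deterministic artifacts are written: the aggregated feature tables
#' with a provenance sidecar, per-variant selection and evaluation
#' JSONs, boosters, Kaplan-Meier curves as CSV, and a run manifest
#' recording the config fingerprint, seed, per-stage timings and file
#' hashes.
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optional pre-built `sim_cohort` or cohort directory.
#' @param out_dir Optional artifact directory.
#' @return List: `reports` (per variant), `variants` (full per-variant
#'   results), `dataset`, `split`, `manifest`.
#' @export
run_full <- function(cfg = pipeline_config(), cohort = NULL,
                     out_dir = NULL) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, t_from) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t_from,
                                             units = "secs"))
    Sys.time()
  }
  if (is.null(cohort)) {
    cohort <- simulate_cohort(sim_config_from(cfg), keep_volumes = FALSE)
  }
  t1 <- tick("simulate", t0)
  dataset <- assemble_dataset(cohort, cfg)
  t2 <- tick("extract_assemble", t1)
  spec <- split_spec(fractions = cfg$split$fractions,
                     strata_keys = cfg$split$strata_keys,
                     inner_val_fraction = cfg$split$inner_val_fraction,
                     seed = derive_seed(cfg$seed, "cohort_split"))
  split <- split_cohort(dataset$strata, spec)
  results <- list()
  for (v in cfg$variants) {
    results[[v]] <- run_variant(dataset, v, split, cfg)
  }
  t3 <- tick("model", t2)
  reports <- lapply(results, `[[`, "report")
  manifest <- list(
    package_version = as.character(utils::packageVersion("radlung")),
    seed = cfg$seed,
    config_fingerprint = object_md5(unclass(cfg)),
    n_patients = nrow(dataset$strata),
    split_sizes = lengths(split),
    timings_s = timings,
    files = list())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    wr <- function(name, writer) {
      p <- file.path(out_dir, name)
      writer(p)
      paths[[name]] <<- p
    }
    wr("features_radiomic.csv",
       function(p) write.csv(dataset$radiomic, p, row.names = FALSE))
    wr("features_clinical.csv",
       function(p) write.csv(dataset$clinical, p, row.names = FALSE))
    wr("provenance.json", function(p) {
      jsonlite::write_json(as.list(dataset$provenance), p,
                           auto_unbox = TRUE)
    })
    wr("split.json", function(p) {
      jsonlite::write_json(split, p, auto_unbox = FALSE)
    })
    for (v in cfg$variants) {
      tag <- gsub("\\+", "", v)
      res <- results[[v]]
      wr(sprintf("selection_%s.json", tag), function(p) {
        jsonlite::write_json(
          lapply(res$selection, function(s) {
            list(selected = s$selected, votes = as.list(s$votes),
                 per_bootstrap = s$per_bootstrap, seed = s$seed)
          }), p, auto_unbox = TRUE)
      })
      wr(sprintf("eval_%s.json", tag), function(p) {
        jsonlite::write_json(report_to_list(res$report), p,
                             auto_unbox = TRUE, digits = NA)
      })
      wr(sprintf("model_%s.json", tag), function(p) {
        xgboost::xgb.save(res$model$booster, p)
      })
      wr(sprintf("km_%s.csv", tag), function(p) {
        km <- res$report$km_by_group
        curves <- do.call(rbind, lapply(names(km), function(g) {
          k <- km[[g]]
          if (is.null(k)) return(NULL)
          data.frame(group = g, time = k$time, surv = k$surv,
                     n_risk = k$n_risk, stringsAsFactors = FALSE)
        }))
        write.csv(curves, p, row.names = FALSE)
      })
    }
    manifest$files <- lapply(paths, file_md5)
    # manifest written last, atomically
    mtmp <- file.path(out_dir, ".manifest.json.tmp")
    jsonlite::write_json(manifest, mtmp, auto_unbox = TRUE, digits = NA)
    file.rename(mtmp, file.path(out_dir, "manifest.json"))
  }
  list(reports = reports, variants = results, dataset = dataset,
       split = split, manifest = manifest)
}

#' Sensitivity of model performance to the train/test split
#'
#' Repeats the split -> select -> train -> evaluate cycle over
#' `n_splits` random stratified splits of the same assembled dataset
#' and summarizes the held-out concordance index per variant by its
#' mean and empirical 2.5-97.5 percentile band. Individual failed
#' splits are recorded and skipped; at least `min_success` must
#' succeed.
#'
#' @param dataset From [assemble_dataset()].
#' @param cfg A [pipeline_config()].
#' @param n_splits Number of random splits.
#' @param seed Master seed for the replicate splits.
#' @param min_success Minimum successful splits required.
#' @return List: `summary` (data.frame variant / mean / lo / hi / n),
#'   `c_index` (matrix splits x variants), `failures`.
#' @export
split_sensitivity <- function(dataset, cfg = pipeline_config(),
                              n_splits = 10, seed = cfg$seed,
                              min_success = max(1, ceiling(0.8 * n_splits))) {
  variants <- cfg$variants
  ci <- matrix(NA_real_, n_splits, length(variants),
               dimnames = list(NULL, variants))
  failures <- list()
  for (r in seq_len(n_splits)) {
    rseed <- derive_seed(seed, "replicate", r)
    res <- tryCatch({
      spec <- split_spec(fractions = cfg$split$fractions,
                         strata_keys = cfg$split$strata_keys,
                         inner_val_fraction = cfg$split$inner_val_fraction,
                         seed = rseed)
      split <- split_cohort(dataset$strata, spec)
      vapply(variants, function(v) {
        run_variant(dataset, v, split, cfg, seed = rseed)$report$c_index
      }, numeric(1))
    }, error = function(e) {
      failures[[length(failures) + 1]] <<-
        list(split = r, message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) ci[r, ] <- res
  }
  ok <- rowSums(!is.na(ci)) == length(variants)
  assert_that(sum(ok) >= min_success,
              "only %d of %d splits succeeded", sum(ok), n_splits)
  summ <- do.call(rbind, lapply(variants, function(v) {
    x <- ci[ok, v]
    data.frame(variant = v, mean = mean(x),
               lo = if (length(x) > 1) quantile(x, 0.025, names = FALSE)
                    else x,
               hi = if (length(x) > 1) quantile(x, 0.975, names = FALSE)
                    else x,
               n = length(x), stringsAsFactors = FALSE)
  }))
  list(summary = summ, c_index = ci[ok, , drop = FALSE],
       failures = failures)
}
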