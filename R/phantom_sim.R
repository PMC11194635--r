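# Synthetic cohort generator: CT lung phantoms with risk-linked texture
# heterogeneity, clinical covariates partially informative of hazard,
# and right-censored Weibull survival times under proportional hazards.
#
# The imaging signal: each phantom holds two ellipsoidal "lungs" of
# aerated parenchyma (~ -850 HU) in an air background, seeded with
# small bright vessel-like blobs (risk-independent) plus a number of
# larger, brighter lesion-like blobs whose count, amplitude and size
# all increase with the patient's latent risk z. After the standard
# [-120, 300] HU clip the parenchyma saturates at the floor and the
# blobs remain as bright structure, so patch heterogeneity features
# (GLCM contrast, NGTDM contrast, first-order variance) are monotone in
# z in expectation -- higher texture heterogeneity, shorter survival.

#' Synthetic cohort configuration
#'
#' Geometry defaults emulate routine thoracic CT (0.8 mm in-plane, 4 mm
#' slices, with per-patient jitter matching the observed spread of
#' clinical acquisitions); the survival scale is calibrated so the
#' baseline cohort median is 332 days.
#'
#' @param n_patients Number of patients (>= 2).
#' @param grid Voxel grid dimensions (nx, ny, nz).
#' @param spacing_mm Mean voxel spacing in mm (x, y, z).
#' @param spacing_sd_mm Per-patient SD of the spacing draw (set to
#'   `c(0,0,0)` for identical geometry).
#' @param beta_radiomic Log-hazard coefficient of the latent risk z.
#' @param beta_clinical Named log-hazard coefficients of the clinical
#'   covariates (see [clinical_eta()] for the reference centering).
#' @param baseline_median_days Cohort median survival at eta = 0.
#' @param censor_horizon_days Upper bound of the uniform censoring
#'   time; `Inf` disables censoring.
#' @param weibull_shape Weibull shape (> 1: increasing hazard).
#' @param missing_rate Probability a patient's released clinical record
#'   has a missing value (exercises the exclusion rule).
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 40, grid = c(96, 96, 48),
                       spacing_mm = c(0.8, 0.8, 4.0),
                       spacing_sd_mm = c(0.08, 0.08, 0.8),
                       beta_radiomic = 0.8,
                       beta_clinical = default_beta_clinical(),
                       baseline_median_days = 332,
                       censor_horizon_days = 1826,
                       weibull_shape = 1.2, missing_rate = 0.03,
                       seed = 1L) {
  assert_that(is_count(n_patients) && n_patients >= 2,
              "n_patients must be >= 2")
  assert_that(length(grid) == 3 && all(grid >= 8), "grid too small")
  assert_that(all(spacing_mm > 0), "spacing must be positive")
  assert_that(baseline_median_days > 0, "baseline median must be > 0")
  assert_that(all(is.finite(beta_clinical)) && is.finite(beta_radiomic),
              "betas must be finite")
  structure(list(n_patients = as.integer(n_patients),
                 grid = as.integer(grid),
                 spacing_mm = as.numeric(spacing_mm),
                 spacing_sd_mm = as.numeric(spacing_sd_mm),
                 beta_radiomic = beta_radiomic,
                 beta_clinical = beta_clinical,
                 baseline_median_days = baseline_median_days,
                 censor_horizon_days = censor_horizon_days,
                 weibull_shape = weibull_shape,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default clinical log-hazard coefficients
#'
#' Worse performance status, higher neutrophil count, lower albumin,
#' higher age and a smoking history increase the hazard; magnitudes are
#' chosen so the clinical signal is moderately stronger than the
#' radiomic one, the ordering seen in immunotherapy survival models.
#'
#' @return Named numeric vector.
#' @export
default_beta_clinical <- function() {
  c(age = 0.02, sex_F = -0.20, smoking_ever = 0.25, ecog_1 = 1.15,
    treatment_combo = -0.13, albumin = -0.10, log_neutrophils = 1.3)
}

#' Clinical component of the linear predictor
#'
#' Covariates are centered at documented reference values (age 63,
#' albumin 40 g/L, neutrophil count 5) so eta = 0 corresponds to the
#' reference patient and the baseline median applies there.
#'
#' @param clinical Data.frame from [simulate_clinical()].
#' @param beta Named coefficients as in [default_beta_clinical()].
#' @return Numeric linear predictor vector.
#' @export
clinical_eta <- function(clinical, beta = default_beta_clinical()) {
  beta["age"] * (clinical$age - 63) +
    beta["sex_F"] * (clinical$sex == "F") +
    beta["smoking_ever"] * (clinical$smoking == "ever") +
    beta["ecog_1"] * (clinical$ecog == "1") +
    beta["treatment_combo"] * (clinical$treatment == "combo") +
    beta["albumin"] * (clinical$albumin - 40) +
    beta["log_neutrophils"] * (log(clinical$neutrophils) - log(5))
}

# Lesion-like blob parameters as functions of latent risk z (clamped to
# [-2, 2] so tails stay physical).
risk_blob_params <- function(z) {
  zc <- pmin(pmax(z, -2), 2)
  list(count = max(1L, as.integer(round(5 + 2.5 * zc))),
       amp_mean = 800 + 150 * zc,
       sigma_max = max(2.2, 3.0 + 0.5 * zc))
}

# Add a Gaussian blob of amplitude `amp` and width `sigma_mm` centered
# at voxel `ctr` (1-based), evaluated on a local +-3 sigma window.
add_blob <- function(vox, ctr, amp, sigma_mm, spacing) {
  d <- dim(vox)
  rad <- pmax(1L, as.integer(ceiling(3 * sigma_mm / spacing)))
  lo <- pmax(ctr - rad, 1L)
  hi <- pmin(ctr + rad, d)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx2 <- ((ii - ctr[1]) * spacing[1])^2
  dy2 <- ((jj - ctr[2]) * spacing[2])^2
  dz2 <- ((kk - ctr[3]) * spacing[3])^2
  g <- outer(outer(dx2, dy2, "+"), dz2, "+")
  vox[ii, jj, kk] <- vox[ii, jj, kk] +
    amp * exp(-g / (2 * sigma_mm^2))
  vox
}

#' Simulate one lung CT phantom
#'
#' Two ellipsoidal lungs in a -1000 HU background; parenchyma at -850
#' HU with Gaussian noise; risk-independent vessel-like blobs plus
#' lesion-like blobs whose count, amplitude and correlation length
#' increase with the latent risk `z`. Deterministic given `(z, seed)`.
#'
#' @param z Latent risk score (standard-normal scale).
#' @param cfg A [sim_config()].
#' @param seed Integer seed for this volume.
#' @param spacing Voxel spacing override in mm (defaults to
#'   `cfg$spacing_mm`).
#' @param patient_id Identifier attached to the volume.
#' @return List with `vol` (a [ct_volume()]) and `roi` (a
#'   [lung_roi()]).
#' @export
simulate_volume <- function(z, cfg = sim_config(), seed = cfg$seed,
                            spacing = cfg$spacing_mm,
                            patient_id = "phantom") {
  d <- cfg$grid
  xi <- (seq_len(d[1]) - 0.5) / d[1]
  yj <- (seq_len(d[2]) - 0.5) / d[2]
  zk <- (seq_len(d[3]) - 0.5) / d[3]
  ell <- function(cx) {
    outer(outer(((xi - cx) / 0.14)^2, ((yj - 0.5) / 0.28)^2, "+"),
          ((zk - 0.5) / 0.40)^2, "+") <= 1
  }
  mask <- ell(0.30) | ell(0.70)
  vox <- with_seed(seed, {
    v <- array(-1000, dim = d)
    nlung <- sum(mask)
    v[mask] <- -850 + rnorm(nlung, sd = 30)
    lung_idx <- which(mask, arr.ind = TRUE)
    # vessel-like blobs: density tied to lung volume, independent of z
    n_vessel <- max(8L, as.integer(round(nlung / 3000)))
    vi <- sample.int(nrow(lung_idx), n_vessel, replace = TRUE)
    vamp <- runif(n_vessel, 650, 850)
    vsig <- runif(n_vessel, 1.5, 3.0)
    for (b in seq_len(n_vessel)) {
      v <- add_blob(v, lung_idx[vi[b], ], vamp[b], vsig[b], spacing)
    }
    # lesion-like blobs: count/amplitude/size increase with risk
    rp <- risk_blob_params(z)
    li <- sample.int(nrow(lung_idx), rp$count, replace = TRUE)
    lamp <- rnorm(rp$count, mean = rp$amp_mean, sd = 50)
    lsig <- runif(rp$count, 2.0, rp$sigma_max)
    for (b in seq_len(rp$count)) {
      v <- add_blob(v, lung_idx[li[b], ], lamp[b], lsig[b], spacing)
    }
    v
  })
  list(vol = ct_volume(vox, spacing = spacing, patient_id = patient_id),
       roi = lung_roi(mask, kind = "mask"))
}

#' Simulate a clinical covariate table
#'
#' Demographics and blood work drawn from parametric distributions
#' matching a metastatic lung cancer trial population (31% female, age
#' 63 +- 9.7, three contributing studies, PD-L1 status at a fixed
#' cutoff). Includes a deliberately collinear pair (`alp`,
#' `alp_ukat` -- the same enzyme activity in different units) to
#' exercise the correlated-feature reduction.
#'
#' @param n Number of patients.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param patient_ids Optional identifiers (defaults to `P0001`...).
#' @return Data.frame with one row per patient; complete (missingness
#'   is injected separately by [simulate_cohort()]).
#' @export
simulate_clinical <- function(n, cfg = sim_config(), seed = cfg$seed,
                              patient_ids = NULL) {
  assert_that(n >= 2, "n must be >= 2")
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  with_seed(seed, {
    alp <- rlnorm(n, log(90), 0.30)
    data.frame(
      patient_id = patient_ids,
      study = sample(c("STUDY_A", "STUDY_B", "STUDY_C"), n,
                     replace = TRUE, prob = c(0.35, 0.40, 0.25)),
      pd_l1 = sample(c("neg", "pos"), n, replace = TRUE,
                     prob = c(0.61, 0.39)),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.69, 0.31)),
      smoking = sample(c("never", "ever"), n, replace = TRUE,
                       prob = c(0.3, 0.7)),
      ecog = sample(c("0", "1"), n, replace = TRUE, prob = c(0.4, 0.6)),
      treatment = sample(c("mono", "combo"), n, replace = TRUE),
      age = rnorm(n, 63, 9.7),
      bmi = rnorm(n, 25.5, 4.5),
      neutrophils = rlnorm(n, log(5), 0.35),
      lymphocytes = rlnorm(n, log(1.6), 0.35),
      albumin = rnorm(n, 40, 4.5),
      alp = alp,
      alp_ukat = alp / 60 * exp(rnorm(n, 0, 0.01)),
      ggt = rlnorm(n, log(45), 0.5),
      stringsAsFactors = FALSE)
  })
}

#' Clinical schema matching [simulate_clinical()]
#'
#' `study` and `pd_l1` are stratification metadata, not features, so
#' they are not part of the schema.
#'
#' @return A [clinical_schema()].
#' @export
sim_clinical_schema <- function() {
  clinical_schema(
    categorical = c("sex", "smoking", "ecog", "treatment"),
    numeric = c("age", "bmi", "neutrophils", "lymphocytes", "albumin",
                "alp", "alp_ukat", "ggt"))
}

#' Simulate right-censored survival times under proportional hazards
#'
#' Event times are Weibull with shape `cfg$weibull_shape` and scale
#' solved in closed form so the median at eta = 0 equals
#' `cfg$baseline_median_days`; the hazard is multiplied by `exp(eta)`.
#' Censoring is independent Uniform(0, `censor_horizon_days`).
#'
#' @param eta Linear predictor vector (one entry per patient).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param patient_ids Optional identifiers.
#' @return A [survival_records()] data.frame.
#' @export
simulate_survival <- function(eta, cfg = sim_config(), seed = cfg$seed,
                              patient_ids = NULL) {
  assert_that(all(is.finite(eta)), "eta must be finite")
  n <- length(eta)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  k <- cfg$weibull_shape
  lambda <- cfg$baseline_median_days / log(2)^(1 / k)
  with_seed(seed, {
    u <- runif(n)
    t_event <- lambda * (-log(u) / exp(eta))^(1 / k)
    if (is.finite(cfg$censor_horizon_days)) {
      cens <- runif(n, 0, cfg$censor_horizon_days)
    } else {
      cens <- rep(Inf, n)
    }
    time <- pmax(pmin(t_event, cens), 1e-3)
    survival_records(patient_ids, time, as.integer(t_event <= cens))
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws a latent risk `z ~ N(0,1)` per patient, links it to imaging
#' heterogeneity via [simulate_volume()] and to the hazard via
#' `eta = beta_radiomic * z + clinical_eta(x)`, and emits every
#' artifact the pipeline consumes. Volumes are regenerable on demand
#' from the stored per-patient seeds, so large cohorts can be processed
#' streaming without holding all voxel data; `keep_volumes = TRUE`
#' materializes them in memory and `out_dir` writes NIfTI volumes and
#' masks plus clinical/survival CSVs.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory for on-disk artifacts.
#' @param keep_volumes Materialize volumes in the returned object.
#' @return A `sim_cohort` list: `clinical` (with missingness injected),
#'   `survival`, `truth` (per-patient `z`, `eta`, spacing, volume
#'   seeds, informative feature names -- never fed to the pipeline),
#'   `volumes` (optional), `cfg`, `paths` (when written).
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir = NULL,
                            keep_volumes = is.null(out_dir) &&
                              cfg$n_patients <= 60) {
  n <- cfg$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  z <- with_seed(derive_seed(cfg$seed, "z"), rnorm(n))
  clinical <- simulate_clinical(n, cfg, derive_seed(cfg$seed, "clinical"),
                                patient_ids = ids)
  eta <- cfg$beta_radiomic * z + clinical_eta(clinical, cfg$beta_clinical)
  records <- simulate_survival(eta, cfg,
                               derive_seed(cfg$seed, "survival"),
                               patient_ids = ids)
  spacing <- with_seed(derive_seed(cfg$seed, "spacing"), {
    t(vapply(seq_len(n), function(i) {
      pmax(cfg$spacing_mm + rnorm(3, 0, cfg$spacing_sd_mm),
           0.25 * cfg$spacing_mm)
    }, numeric(3)))
  })
  vol_seeds <- vapply(ids, function(pid) derive_seed(cfg$seed, "volume",
                                                     pid), integer(1))
  # inject missingness into the released clinical table only
  clinical_out <- clinical
  miss <- with_seed(derive_seed(cfg$seed, "missing"),
                    runif(n) < cfg$missing_rate)
  clinical_out$albumin[miss] <- NA_real_
  truth <- list(
    patient_id = ids, z = z, eta = as.numeric(eta),
    eta_clinical = as.numeric(clinical_eta(clinical, cfg$beta_clinical)),
    spacing = spacing, volume_seed = vol_seeds,
    # the latent factor enters as bright-structure density, so every
    # heterogeneity readout responds; these base features are monotone
    # in z by construction (their aggregates are the recoverable signal)
    informative_radiomic_base = c(
      "firstorder.mean", "firstorder.variance", "firstorder.energy",
      "firstorder.maximum", "glcm.contrast", "glcm.joint_entropy",
      "glcm.correlation", "glrlm.short_run_emphasis",
      "glrlm.run_percentage", "glszm.zone_percentage",
      "gldm.small_dependence_emphasis", "ngtdm.contrast",
      "ngtdm.busyness", "ngtdm.coarseness"),
    informative_clinical = c("ecog_1", "albumin", "log_neutrophils"),
    seed = cfg$seed)
  volumes <- NULL
  if (keep_volumes) {
    volumes <- lapply(seq_len(n), function(i) {
      simulate_volume(z[i], cfg, seed = vol_seeds[i],
                      spacing = spacing[i, ], patient_id = ids[i])
    })
    names(volumes) <- ids
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_len(n)) {
      vr <- if (keep_volumes) volumes[[i]] else {
        simulate_volume(z[i], cfg, seed = vol_seeds[i],
                        spacing = spacing[i, ], patient_id = ids[i])
      }
      write_volume(vr$vol, file.path(img_dir,
                                     paste0(ids[i], "_ct.nii.gz")))
      write_mask(vr$roi, vr$vol,
                 file.path(img_dir, paste0(ids[i], "_mask.nii.gz")))
    }
    write.csv(clinical_out, file.path(out_dir, "clinical.csv"),
              row.names = FALSE)
    write.csv(records, file.path(out_dir, "survival.csv"),
              row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "sim_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- list(images = img_dir,
                  clinical = file.path(out_dir, "clinical.csv"),
                  survival = file.path(out_dir, "survival.csv"),
                  truth = file.path(out_dir, "sim_truth.json"))
  }
  structure(list(clinical = clinical_out, survival = records,
                 truth = truth, volumes = volumes, cfg = cfg,
                 paths = paths),
            class = "sim_cohort")
}

#' Regenerate (or fetch) one patient's phantom volume
#'
#' @param cohort A `sim_cohort`.
#' @param patient_id Patient identifier.
#' @return List `vol`, `roi` as from [simulate_volume()].
#' @export
cohort_volume <- function(cohort, patient_id) {
  if (!is.null(cohort$volumes)) return(cohort$volumes[[patient_id]])
  i <- match(patient_id, cohort$truth$patient_id)
  assert_that(!is.na(i), "unknown patient_id %s", patient_id)
  simulate_volume(cohort$truth$z[i], cohort$cfg,
                  seed = cohort$truth$volume_seed[i],
                  spacing = cohort$truth$spacing[i, ],
                  patient_id = patient_id)
}
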