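# radlung

Annotation-free whole-lung CT radiomics for survival risk prediction in
metastatic non-small-cell lung cancer.

Most radiomic survival models require a radiologist to delineate the
target tumor slice by slice. `radlung` implements the alternative:
features are extracted from `n = 80` cubic 3D patches of 5 cm³ sampled
uniformly across the whole lung region, with no lesion segmentation at
all. Per-patch first-order and texture features (GLCM, GLRLM, GLSZM,
GLDM, NGTDM; IBSI-style definitions) are aggregated per patient by
eight summary statistics, reduced by bootstrapped Spearman +
mutual-information selection (5 bootstraps, ≥ 2 votes), and fed to an
XGBoost classifier of one-year overall survival with a Youden-optimal
decision threshold. Three variants share one split and one code path:

* **Model-C** — clinical covariates only,
* **Model-R** — whole-lung radiomic features only,
* **Model-C+R** — the union of both selected feature sets.

Evaluation covers accuracy/sensitivity/specificity/precision, ROC/AUC
(Mann-Whitney, ties ½), Kaplan-Meier stratification with median
separation, the log-rank test, the Cox proportional-hazards ratio
(Breslow ties), Harrell's concordance index (risk = 1 − survival
score), and a 10-split sensitivity analysis reporting the empirical
2.5–97.5 percentile band.

Clinical trial imaging cannot be redistributed, so the package includes
a synthetic cohort generator: CT lung phantoms whose texture
heterogeneity (lesion-like blob count, amplitude, size) increases with
a latent risk score `z`, clinical covariates partially informative of
hazard, and Weibull survival times under proportional hazards
(`eta = beta_radiomic * z + x' beta_clinical`, baseline median 332
days, uniform censoring). The whole pipeline is exercisable and tested
end to end with no external data; see the methods vignette
(`vignettes/whole-lung-radiomics.Rmd`) for the model, parameter, and
design discussion.

## Worked example

A desk-scale synthetic run — 120 patients, 20 patches each — from
simulation through evaluation:

```r
library(radlung)
cfg <- pipeline_config(list(sim = list(n_patients = 120),
                            sampling = list(n_patches = 20)), seed = 42)
res <- run_full(cfg)
res$reports[["C+R"]]
#> <eval_report> n=22 (labelable 21)
#>   accuracy 0.571  sens 1.000  spec 0.526  prec 0.182
#>   AUC 0.789  c-index 0.649  HR 2.18 [0.87, 5.44]  log-rank p 0.0891
#>   median separation 19.01633 days
```

Reading the report: of the 22 held-out patients, 21 have a knowable
one-year status (one was censored before day 365 and is excluded from
the classification metrics but kept in the time-to-event metrics). The
combined model's score ranks survival with concordance 0.649, and
patients it calls "model-negative" (predicted OS < 365 days) die at
2.18 times the hazard of model-positive patients. At this cohort size
the confidence intervals are wide and single-split accuracies are
noisy; the stable comparisons come from `split_sensitivity()`, which
repeats split → select → train → evaluate over 10 random stratified
splits:

```r
cohort  <- simulate_cohort(sim_config(n_patients = 400, seed = 3),
                           keep_volumes = FALSE)
dataset <- assemble_dataset(cohort, pipeline_config(
  list(sim = list(n_patients = 400), sampling = list(n_patches = 20)),
  seed = 3))
split_sensitivity(dataset, cfg, n_splits = 10)$summary
#>   variant      mean        lo        hi  n
#> 1       C 0.6214077 0.5627164 0.6577258 10
#> 2       R 0.6042305 0.5377106 0.6519601 10
#> 3     C+R 0.6814857 0.6101647 0.7219122 10
```

The clinical model edges out the radiomic one and the combined model
beats both — the hierarchy this class of models shows on real trial
cohorts.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/radlung.R", package="radlung"))') \
    run-full --seed 7 --out run/
```

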