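# Memoised fixtures shared across test files: the large synthetic
# cohort used by the recovery experiments is built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Recovery-experiment configuration: default generator conditions with
# imaging at a reduced 20 patches/patient for tractable extraction.
recovery_cfg <- function() {
  pipeline_config(list(sim = list(n_patients = 400),
                       sampling = list(n_patches = 20)), seed = 3)
}

recovery_cohort <- function() {
  cached_fixture("recovery_cohort", function() {
    simulate_cohort(radlung:::sim_config_from(recovery_cfg()),
                    keep_volumes = FALSE)
  })
}

recovery_dataset <- function() {
  cached_fixture("recovery_dataset", function() {
    assemble_dataset(recovery_cohort(), recovery_cfg())
  })
}

strip_stat_suffix <- function(feature_names) {
  unique(sub("\\.(mean|median|min|max|sum|mad|skew|kurtosis)$", "",
             feature_names))
}
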