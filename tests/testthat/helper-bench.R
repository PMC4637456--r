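# Packaged synthetic benchmark shared across test files. A one-third-scale
# replica of the study imbalance (21/18/354/7 mirroring 63/55/1061/20, with
# the SMOTE target scaled 60 -> 20), moderate composition and PSSM signal,
# and a reduced feature configuration. Expensive cross-validation results
# are computed once per session and cached.

.bench_cache <- new.env(parent = emptyenv())

cache_get <- function(name, build) {
  if (!exists(name, envir = .bench_cache)) {
    assign(name, build(), envir = .bench_cache)
  }
  get(name, envir = .bench_cache)
}

bench_feature_config <- function() {
  feature_config(lnc = 15, gamma_max = 4, lambda_max = 3)
}

bench_ensemble_config <- function(...) {
  ensemble_config(n_subsets = 20, smote_target = 20, smote_k = 3,
                  rf_ntree = 80, seed = 5, ...)
}

bench_sim_config <- function(composition_bias = 0.35, pssm_signal = 1.5,
                             seed = 42) {
  sim_config(class_counts = c(I = 21, II = 18, III = 354, IV = 7),
             length_range = c(60, 100),
             composition_bias = composition_bias,
             pssm_signal = pssm_signal, seed = seed)
}

bench_features <- function() {
  cache_get("fm", function() {
    feature_matrix(simulate_dataset(bench_sim_config()),
                   bench_feature_config())
  })
}

bench_cv_ensemble <- function() {
  cache_get("cv_ens", function() {
    fm <- bench_features()
    cross_validate(fm, attr(fm, "labels"), bench_ensemble_config(),
                   n_folds = 3, seed = 9)
  })
}

bench_cv_rf <- function() {
  cache_get("cv_rf", function() {
    fm <- bench_features()
    cross_validate(fm, attr(fm, "labels"), bench_ensemble_config(),
                   n_folds = 3, seed = 9, model = "random-forest")
  })
}

# No-signal null: same sizes, zero composition bias and PSSM signal,
# evaluated with the leakage-free SMOTE scope so synthetic minority rows
# cannot advertise their training neighbourhoods to the test folds.
bench_cv_null <- function() {
  cache_get("cv_null", function() {
    fm <- feature_matrix(
      simulate_dataset(bench_sim_config(composition_bias = 0,
                                        pssm_signal = 0, seed = 43)),
      bench_feature_config())
    cross_validate(fm, attr(fm, "labels"),
                   bench_ensemble_config(smote_scope = "train_fold_only"),
                   n_folds = 3, seed = 9)
  })
}

per_class_sn <- function(cv_metrics) {
  stats::setNames(cv_metrics$per_class$sn, cv_metrics$per_class$class)
}
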