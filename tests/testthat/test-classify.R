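test_that("a cleanly separated cohort classifies perfectly", {
  coh <- generate_cohort(separable_cohort_config(seed = 11))
  ft <- build_feature_table(coh$traces)
  rep <- run_cv(ft, experiment_spec("two_way", seed = 1,
                                    imputation_mode = "complete_only",
                                    downslope_horizon_added_s = 100))
  expect_gte(rep$mean_auc, 0.99)
  expect_identical(length(rep$per_fold_auc), 5L)
  expect_equal(rep$mean_auc, mean(rep$per_fold_auc))
})

test_that("reports are deterministic under identical seed and inputs", {
  d <- default_cohort(1)
  spec <- experiment_spec("two_way", seed = 7)
  r1 <- run_cv(d$features, spec, normalized = d$normalized)
  r2 <- run_cv(d$features, spec, normalized = d$normalized)
  expect_identical(r1$per_fold_auc, r2$per_fold_auc)
  expect_identical(r1$mean_auc, r2$mean_auc)
  expect_identical(r1$per_fold_classifier, r2$per_fold_classifier)
  expect_identical(r1$n_imputed_cells, r2$n_imputed_cells)
})

test_that("fold fitting depends on training rows only", {
  d <- default_cohort(1)
  ft <- d$features
  spec <- experiment_spec("two_way", seed = 3)
  train <- ft[1:200, ]
  probe <- ft[201:210, ]

  set.seed(1)
  fitA <- fit_fold(train, spec)
  set.seed(1)
  fitB <- fit_fold(train, spec)
  # identical fitted state regardless of what test rows exist elsewhere
  expect_identical(fitA$imputed_table, fitB$imputed_table)
  expect_identical(fitA$center, fitB$center)
  expect_identical(fitA$classifier, fitB$classifier)
  pA <- predict_fold(fitA, probe, d$normalized)
  pB <- predict_fold(fitB, probe, d$normalized)
  expect_identical(pA$probs, pB$probs)
  # dropping a test row changes nothing about the fit or other predictions
  pA_sub <- predict_fold(fitA, probe[-3, ], d$normalized)
  expect_identical(pA$probs[-3, ], pA_sub$probs)
})

test_that("permuted labels score at chance", {
  d <- default_cohort(1)
  aucs <- vapply(1:4, function(r) {
    ftp <- d$features
    set.seed(300 + r)
    ftp$class <- sample(ftp$class)
    run_cv(ftp, cheap_spec(seed = r, downslope_horizon_added_s = 100))$mean_auc
  }, numeric(1))
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})

test_that("within-fold imputation completes all requested horizons", {
  d <- default_cohort(1)
  spec <- experiment_spec("two_way", seed = 5)
  rep <- run_cv(d$features, spec, normalized = d$normalized,
                return_details = TRUE)
  expect_gt(rep$n_imputed_cells, 0)
  for (f in seq_along(rep$details)) {
    fit <- rep$details[[f]]$fit
    feats <- fit$features
    expect_false(anyNA(fit$imputed_table[feats]))
  }
})

test_that("complete_only equals imputed when nothing is missing", {
  cfg <- separable_cohort_config(seed = 12)
  coh <- generate_cohort(cfg)
  ft <- build_feature_table(coh$traces)
  stopifnot(sum(missingness_summary(ft)[c("ds10", "ds50", "ds100")]) == 0)
  a <- run_cv(ft, experiment_spec("two_way", seed = 2,
                                  imputation_mode = "imputed",
                                  downslope_horizon_added_s = 100))
  b <- run_cv(ft, experiment_spec("two_way", seed = 2,
                                  imputation_mode = "complete_only",
                                  downslope_horizon_added_s = 100))
  expect_identical(a$per_fold_auc, b$per_fold_auc)
})

test_that("incremental experiment mirrors the horizon-by-policy table", {
  coh <- generate_cohort(cohort_config(
    n_patients = 12, rois_per_class = c(healthy = 30, benign = 14,
                                        cancer = 36),
    patient_lesion_split = c(benign = 4, cancer = 8), seed = 8))
  ft <- build_feature_table(coh$traces)
  norm <- prepare_normalized(coh$traces)
  tab <- incremental_feature_experiment(
    ft, split_mode = "two_way", horizons_s = c(50, 400),
    normalized = norm, seed = 2, candidates = "bagged_knn", knn_k_grid = 5)
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$imputation_mode, c("complete_only", "imputed"))
  expect_true(all(tab$mean_auc >= 0 & tab$mean_auc <= 1))
  n_miss_400 <- missingness_summary(ft)[["ds400"]]
  imput_400 <- tab$n_imputed_cells[tab$horizon_s == 400 &
                                   tab$imputation_mode == "imputed"]
  expect_gte(imput_400, n_miss_400)
  # complete-data rows drop the interrupted ROIs instead of imputing
  expect_identical(tab$n_imputed_cells[tab$imputation_mode ==
                                       "complete_only"], c(0L, 0L))
})

test_that("three-way classification reports macro one-vs-rest AUC", {
  d <- default_cohort(1)
  rep <- run_cv(d$features, experiment_spec("three_way", seed = 4,
                                            downslope_horizon_added_s = 100,
                                            candidates = "bagged_knn"),
                normalized = d$normalized)
  expect_true(rep$mean_auc > 0.5 && rep$mean_auc <= 1)
})

test_that("patient-level folds never split a patient", {
  d <- default_cohort(1)
  spec <- experiment_spec("two_way", seed = 6, grouping = "patient_level",
                          candidates = "bagged_knn",
                          downslope_horizon_added_s = 100,
                          imputation_mode = "complete_only")
  set.seed(spec$seed)
  folds <- icgquant:::make_folds(d$features, spec)
  fold_of <- integer(nrow(d$features))
  for (f in seq_along(folds)) fold_of[folds[[f]]] <- f
  spans <- tapply(fold_of, d$features$patient_id,
                  function(v) length(unique(v)))
  expect_true(all(spans == 1))
  rep <- run_cv(d$features, spec)
  expect_true(rep$mean_auc > 0.5)
})

test_that("stratification failures raise errors", {
  d <- default_cohort(1)
  one_class <- d$features[d$features$class == "cancer", ]
  expect_error(run_cv(one_class, experiment_spec("two_way", seed = 1)),
               "classes")
  tiny <- d$features[c(which(d$features$class == "cancer")[1:3],
                       which(d$features$class == "healthy")[1:30]), ]
  expect_error(run_cv(tiny, experiment_spec("two_way", seed = 1,
                                            imputation_mode =
                                              "complete_only")),
               "stratification")
})

test_that("truncation simulation is a no-op beyond the longest horizon", {
  cfg <- separable_cohort_config(seed = 13)
  coh <- generate_cohort(cfg)
  ft <- build_feature_table(coh$traces)
  norm <- prepare_normalized(coh$traces)
  ts <- truncation_inference_simulation(
    ft, spec = cheap_spec(seed = 3, downslope_horizon_added_s = 100),
    keep_post_peak_s = 500, normalized = norm)
  expect_identical(ts$full$per_fold_auc, ts$truncated$per_fold_auc)
})

test_that("zero-washout cohorts are untouched by truncation + imputation", {
  flat <- kinetic_params(onset_time_s = 5, time_to_peak_s = 15,
                         peak_intensity_gs = 150, washout_rate_per_s = 0,
                         plateau_fraction = 1)
  rising <- kinetic_params(onset_time_s = 5, time_to_peak_s = 15,
                           peak_intensity_gs = 150,
                           washout_rate_per_s = 0.01)
  cfg <- cohort_config(
    n_patients = 10, rois_per_class = c(healthy = 20, cancer = 20),
    patient_lesion_split = c(benign = 0, cancer = 10),
    presets = list(healthy = list(mean = rising, cv = 0.1),
                   cancer = list(mean = flat, cv = 0)),
    artifacts = artifact_config(movement_noise_sd_gs = 0),
    p_double_bolus = 0,
    durations = duration_distribution("fixed", value = 500), seed = 17)
  coh <- generate_cohort(cfg)
  ft <- build_feature_table(coh$traces)
  norm <- prepare_normalized(coh$traces)
  ts <- truncation_inference_simulation(
    ft, spec = cheap_spec(seed = 2, downslope_horizon_added_s = 400),
    keep_post_peak_s = 10, normalized = norm)
  # flat tails impute to their true zero slopes: features barely move
  expect_equal(ts$truncated$mean_auc, ts$full$mean_auc, tolerance = 0.02)
})
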