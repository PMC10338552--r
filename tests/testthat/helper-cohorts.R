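# Shared fixture builders. Everything is generated in code at test time.

# Noiseless single-bolus trace on the sample grid (onset and rise aligned to
# the 5 Hz grid so sampled milestones admit exact closed-form comparison).
noiseless_trace <- function(params, duration_s = 600, fs = 5) {
  generate_trace(params, artifact_config(), sampling_rate_hz = fs,
                 duration_s = duration_s)
}

# Twin-peak regime: first inflow peak ~15 s, second ~25 s (double bolus).
fig2b_artifacts <- function(delay = 10, rel_amp = 0.6, noise_sd = 0) {
  artifact_config(
    double_bolus = list(second_peak_delay_s = delay,
                        second_peak_relative_amplitude = rel_amp),
    movement_noise_sd_gs = noise_sd)
}

fig2b_params <- function() {
  kinetic_params(onset_time_s = 10, time_to_peak_s = 10,
                 peak_intensity_gs = 150, washout_rate_per_s = 0.0067,
                 plateau_fraction = 0)
}

# Small two-class cohort with cleanly separated washout kinetics and no
# acquisition artifacts beyond mild noise: the classifier should be perfect.
separable_cohort_config <- function(seed = 11) {
  cohort_config(
    n_patients = 20,
    rois_per_class = c(healthy = 40, cancer = 40),
    patient_lesion_split = c(benign = 0, cancer = 20),
    presets = class_presets(
      cv_spread = 0.05,
      downslope_10 = c(healthy = -0.0065, benign = -0.004,
                       cancer = -0.0005)),
    artifacts = artifact_config(movement_noise_sd_gs = 1),
    p_double_bolus = 0,
    seed = seed)
}

# Two classes that differ only in washout rate (identical inflow timing),
# used to check that widening the washout gap raises downstream AUC.
washout_gap_config <- function(cancer_ds10, seed) {
  k_h <- washout_rate_for_downslope(-0.0065)
  k_c <- washout_rate_for_downslope(cancer_ds10)
  cohort_config(
    n_patients = 20,
    rois_per_class = c(healthy = 40, cancer = 40),
    patient_lesion_split = c(benign = 0, cancer = 20),
    presets = list(
      healthy = list(mean = kinetic_params(5, 20, 150, k_h, 0), cv = 0.3),
      cancer = list(mean = kinetic_params(5, 20, 150, k_c, 0), cv = 0.3)),
    p_double_bolus = 0,
    durations = duration_distribution("fixed", value = 150),
    seed = seed)
}

# Cheap experiment spec for tests that only need a working classifier.
cheap_spec <- function(split_mode = "two_way", seed = 1,
                       downslope_horizon_added_s = 50, ...) {
  experiment_spec(split_mode = split_mode, seed = seed,
                  imputation_mode = "complete_only",
                  downslope_horizon_added_s = downslope_horizon_added_s,
                  candidates = "bagged_knn", knn_k_grid = 5, ...)
}

# The default paper-anchored cohort is expensive enough to build once and
# share across test files.
default_cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(default_cohort_cache[[key]])) {
    coh <- generate_cohort(cohort_config(seed = seed))
    ft <- build_feature_table(coh$traces)
    default_cohort_cache[[key]] <- list(
      traces = coh$traces, manifest = coh$manifest, features = ft,
      normalized = prepare_normalized(coh$traces))
  }
  default_cohort_cache[[key]]
}
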