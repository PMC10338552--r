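test_that("zero-decay parameters give a constant post-peak tail", {
  p <- kinetic_params(onset_time_s = 5, time_to_peak_s = 20,
                      peak_intensity_gs = 150, washout_rate_per_s = 0,
                      plateau_fraction = 1)
  tr <- noiseless_trace(p, duration_s = 120)
  post <- tr$intensity[tr$time_s >= analytic_tmax(p)]
  expect_true(all(post == 150))
})

test_that("normalized tail slopes of noiseless traces match the closed form", {
  # ((plateau + (1 - plateau) e^{-kN}) - 1)/N, checked to 1e-9
  presets <- class_presets()
  for (cls in names(presets)) {
    p <- presets[[cls]]$mean
    tr <- noiseless_trace(p, duration_s = 600)
    nt <- normalize_trace(tr)
    ms <- extract_milestones(nt)
    for (N in c(10, 50, 100, 200)) {
      expect_equal(ms[[paste0("ds", N)]], analytic_downslope(p, N),
                   tolerance = 1e-9)
    }
  }
})

test_that("healthy preset downslope_10 reproduces the healthy outflow slope", {
  p <- class_presets()$healthy$mean
  tr <- noiseless_trace(p, duration_s = 300)
  ms <- extract_milestones(normalize_trace(tr))
  expect_equal(ms$ds10, -0.0065, tolerance = 1e-4)
})

test_that("double bolus yields two local maxima near 15 s and 25 s", {
  tr <- generate_trace(fig2b_params(), fig2b_artifacts(delay = 10),
                       duration_s = 120)
  pk <- find_peaks(tr$intensity)
  pk <- pk[pk$prominence >= 0.15 * max(tr$intensity), ]
  expect_identical(nrow(pk), 2L)
  expect_equal(tr$time_s[pk$index], c(15, 25), tolerance = 1)
})

test_that("cohort generation is deterministic under config + seed", {
  cfg <- cohort_config(n_patients = 6,
                       rois_per_class = c(healthy = 8, benign = 4,
                                          cancer = 8),
                       patient_lesion_split = c(benign = 2, cancer = 4),
                       seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  for (i in seq_along(a$traces))
    expect_identical(a$traces[[i]]$intensity, b$traces[[i]]$intensity)
})

test_that("default cohort mirrors the emulated clinical series", {
  d <- default_cohort(1)
  expect_identical(length(d$traces), 251L)
  expect_identical(length(unique(d$manifest$patient_id)), 37L)
  counts <- table(d$manifest$class)
  expect_identical(as.integer(counts[c("healthy", "benign", "cancer")]),
                   c(88L, 46L, 117L))
  # every trace carries exactly one class and one patient
  expect_false(anyNA(d$manifest$class))
  expect_false(anyNA(d$manifest$patient_id))
  # duration quota realises the interrupted-series profile by construction:
  # 11 / 72 / 106 traces end before the 200 / 300 / 400 s horizons
  short_of <- function(N) sum(d$manifest$duration_s <
                                d$manifest$t_peak_s + N)
  expect_identical(short_of(200), 11L)
  expect_identical(short_of(300), 72L)
  expect_identical(short_of(400), 106L)
  expect_identical(short_of(100), 0L)
})

test_that("saturated traces pin at the ceiling for a sustained run", {
  p <- class_presets()$healthy$mean
  tr <- generate_trace(p, artifact_config(enable_saturation = TRUE),
                       duration_s = 200)
  r <- rle(tr$intensity >= 255)
  expect_true(any(r$lengths[r$values] >= 3))
  expect_true(all(tr$intensity <= 255))
})

test_that("frame stacks round-trip traces and respect the pixel range", {
  p <- kinetic_params(onset_time_s = 2, time_to_peak_s = 8,
                      peak_intensity_gs = 200, washout_rate_per_s = 0.02)
  tr <- generate_trace(p, artifact_config(), sampling_rate_hz = 2,
                       duration_s = 30)
  boxes <- data.frame(roi_id = "R1", x0 = 4, y0 = 6, width = 5, height = 4)
  stk <- render_frame_stack(list(tr), boxes, frame_shape = c(24, 24),
                            pixel_noise_sd = 0, seed = 5)
  expect_true(all(stk$frames <= 255) && all(stk$frames >= 0))
  got <- extract_traces(stk$frames, stk$roi_boxes, stk$time_s)[[1]]
  expect_equal(got$intensity, tr$intensity)
})

test_that("two-ROI stack recovers distinct peak intensities", {
  mk <- function(peak) {
    p <- kinetic_params(onset_time_s = 2, time_to_peak_s = 8,
                        peak_intensity_gs = peak,
                        washout_rate_per_s = 0.02)
    generate_trace(p, artifact_config(), sampling_rate_hz = 2,
                   duration_s = 40)
  }
  traces <- list(mk(209.42), mk(82.82))
  boxes <- data.frame(roi_id = c("lesion", "control"),
                      x0 = c(2, 20), y0 = c(2, 20),
                      width = c(8, 8), height = c(8, 8))
  stk <- render_frame_stack(traces, boxes, frame_shape = c(32, 32),
                            pixel_noise_sd = 1, seed = 7)
  got <- extract_traces(stk$frames, stk$roi_boxes, stk$time_s)
  expect_equal(max(got[[1]]$intensity), 209.42, tolerance = 1)
  expect_equal(max(got[[2]]$intensity), 82.82, tolerance = 1)
})

test_that("overlapping ROI boxes are rejected", {
  tr <- noiseless_trace(class_presets()$healthy$mean, duration_s = 60)
  boxes <- data.frame(roi_id = c("a", "b"), x0 = c(0, 3), y0 = c(0, 2),
                      width = c(6, 6), height = c(6, 6))
  expect_error(render_frame_stack(list(tr, tr), boxes,
                                  frame_shape = c(20, 20)),
               "overlap")
})

test_that("empty class configurations are rejected", {
  expect_error(cohort_config(rois_per_class = c(healthy = 0, benign = 0,
                                                cancer = 0)),
               "positive ROI count")
})

test_that("widening the washout gap between classes raises CV AUC", {
  gaps <- c(-0.0055, -0.004, -0.0015)  # cancer ds10 moving away from -0.0065
  mean_aucs <- vapply(gaps, function(g) {
    mean(vapply(1:5, function(s) {
      coh <- generate_cohort(washout_gap_config(g, seed = 30 + s))
      ft <- build_feature_table(coh$traces)
      run_cv(ft, cheap_spec(seed = s, downslope_horizon_added_s = 10,
                            include_upslope = FALSE,
                            include_kurtosis = FALSE))$mean_auc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_aucs) > 0))
})
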