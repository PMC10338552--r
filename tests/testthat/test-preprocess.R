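test_that("hysteresis peak finder matches thresholded topographic prominence", {
  set.seed(42)
  for (i in 1:30) {
    n <- 300
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 8, 8), sides = 1))
    x[is.na(x)] <- 0
    x <- x + sin(seq(0, 6 * pi, length.out = n))
    for (thr in c(0.3, 0.8, 1.5)) {
      pk <- find_peaks(x)
      expect_identical(prominent_peaks(x, thr),
                       pk$index[pk$prominence >= thr])
    }
  }
})

test_that("saturation is flagged for sustained ceiling runs only", {
  fs <- 5
  t <- seq(0, 120, by = 1 / fs)
  x <- pmin(250 * exp(-((t - 40)^2) / 800) * 1.5, 255)
  tr <- fluorescence_trace(t, x)
  sat <- detect_saturation(tr)
  expect_true(sat$saturated)
  expect_gt(sat$saturated_span_s, 2)

  # a 30 s clipped plateau reports a ~30 s span
  x30 <- rep(100, length(t)); x30[t >= 40 & t <= 70] <- 255
  s30 <- detect_saturation(fluorescence_trace(t, x30))
  expect_true(s30$saturated)
  expect_equal(s30$saturated_span_s, 30, tolerance = 0.5)

  # peak 209.42: well below the ceiling
  p <- kinetic_params(peak_intensity_gs = 209.42)
  expect_false(detect_saturation(noiseless_trace(p, 100))$saturated)

  # one isolated ceiling sample is not a plateau
  x1 <- rep(100, length(t)); x1[200] <- 255
  expect_false(detect_saturation(fluorescence_trace(t, x1))$saturated)
})

test_that("double-peak detection separates twin-bolus from single-bolus", {
  tr <- generate_trace(fig2b_params(), fig2b_artifacts(), duration_s = 120)
  dp <- detect_double_peak(tr)
  expect_true(dp$double_peak)
  expect_equal(sort(dp$peak_times_s)[1:2], c(15, 25), tolerance = 1)

  mono <- noiseless_trace(class_presets()$healthy$mean, 200)
  expect_false(detect_double_peak(mono)$double_peak)
})

test_that("noise around a constant yields no prominent peak", {
  set.seed(5)
  t <- seq(0, 60, by = 0.2)
  x <- 100 + rnorm(length(t), 0, 2)
  tr <- fluorescence_trace(t, x)
  # brute-force check that no local maximum reaches the prominence bar
  pk <- find_peaks(x)
  expect_true(all(pk$prominence < 0.15 * max(x)))
  expect_false(detect_double_peak(tr)$double_peak)
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  t <- seq(0, 100, by = 0.2)
  x <- 50 + 0.9 * t - 0.012 * t^2 + 5e-5 * t^3
  stopifnot(all(x > 0 & x < 255))
  tr <- fluorescence_trace(t, x)
  sm <- smooth_trace(tr, window_s = 11, polyorder = 3)
  expect_equal(sm$intensity, x, tolerance = 1e-8)
  # constant trace unchanged
  cn <- fluorescence_trace(t, rep(42, length(t)))
  expect_equal(smooth_trace(cn)$intensity, rep(42, length(t)))
})

test_that("smoothing lowers the RMS error against the noiseless truth", {
  p <- class_presets()$healthy$mean
  clean <- noiseless_trace(p, 300)
  set.seed(9)
  noisy <- clean
  noisy$intensity <- pmin(pmax(clean$intensity +
                                 rnorm(length(clean$intensity), 0, 5),
                               0), 255)
  sm <- smooth_trace(noisy)
  rms <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rms(sm$intensity, clean$intensity),
            rms(noisy$intensity, clean$intensity))
})

test_that("smoothing commutes with affine intensity maps", {
  p <- class_presets()$benign$mean
  tr <- generate_trace(p, artifact_config(movement_noise_sd_gs = 2),
                       duration_s = 120, seed = 4)
  aff <- tr
  aff$intensity <- 0.5 * tr$intensity + 20
  expect_equal(smooth_trace(aff)$intensity,
               0.5 * smooth_trace(tr)$intensity + 20, tolerance = 1e-9)
})

test_that("short traces get an actionable smoothing error", {
  tr <- fluorescence_trace(seq(0, 1.6, by = 0.2), rep(10, 9))
  expect_error(smooth_trace(tr, window_s = 11), "smaller window")
})

test_that("peak normalization records its divisor and is idempotent", {
  p <- kinetic_params(peak_intensity_gs = 209.42, onset_time_s = 2,
                      time_to_peak_s = 10)
  nt <- normalize_trace(noiseless_trace(p, 100))
  expect_equal(max(nt$intensity), 1, tolerance = 1e-9)
  expect_equal(nt$normalization_peak_gs, 209.42)
  again <- normalize_trace(nt)
  expect_equal(again$normalization_peak_gs, 1)
  expect_equal(again$intensity, nt$intensity)
})

test_that("normalization is scale invariant", {
  # identically shaped curves at different absolute intensities collapse
  # onto the same normalized curve (the distance-intensity mitigation)
  p <- kinetic_params(peak_intensity_gs = 82.82, onset_time_s = 3,
                      time_to_peak_s = 12, washout_rate_per_s = 0.01)
  base <- noiseless_trace(p, 150)
  ref <- normalize_trace(base)$intensity
  for (c_scale in c(0.3, 3)) {
    scaled <- base
    scaled$intensity <- base$intensity * c_scale
    expect_equal(normalize_trace(scaled)$intensity, ref, tolerance = 1e-9)
  }
  zero <- fluorescence_trace(0:9, rep(0, 10))
  expect_error(normalize_trace(zero), "normalize")
})

test_that("qc_report flags the artifact regimes per trace", {
  p <- class_presets()$healthy$mean
  traces <- list(
    generate_trace(p, artifact_config(enable_saturation = TRUE),
                   duration_s = 200, seed = 1, trace_id = "sat"),
    generate_trace(fig2b_params(), fig2b_artifacts(noise_sd = 3),
                   duration_s = 120, seed = 2, trace_id = "db"),
    generate_trace(p, artifact_config(movement_noise_sd_gs = 3),
                   duration_s = 200, seed = 3, trace_id = "clean"))
  qc <- qc_report(traces)
  expect_identical(qc$saturated, c(TRUE, FALSE, FALSE))
  expect_identical(qc$double_peak, c(FALSE, TRUE, FALSE))
  expect_true(all(qc$usable_post_peak_s > 0))
})
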