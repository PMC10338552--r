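#' Acquisition-artifact configuration
#'
#' Describes the acquisition artifacts layered on top of the noiseless
#' kinetic curve, in the order they are applied: double bolus (an additive
#' second kinetic curve), movement noise (white Gaussian noise plus a
#' low-frequency sinusoidal oscillation), an optional movement spike
#' (camera lurch toward the target), truncation (video ends early), and
#' finally clipping to the detector range \[0, ceiling\].
#'
#' Detector saturation from overdosing is modelled by `saturation_gain`:
#' when `enable_saturation` is `TRUE` the whole curve is scaled by the gain
#' before clipping, pinning the peak region at the greyscale ceiling and
#' producing the persistent-plateau artifact seen with excessive ICG doses.
#'
#' @param saturation_ceiling_gs Detector ceiling in greyscale units.
#' @param enable_saturation Apply the overdose gain before clipping.
#' @param saturation_gain Multiplicative overdose gain (default 2.0, a
#'   doubled effective dose; must push the curve past the ceiling to
#'   saturate).
#' @param double_bolus `NULL`, or a list with `second_peak_delay_s`,
#'   `second_peak_relative_amplitude` in (0, 1] and optionally
#'   `first_pass_rate_per_s` (default 0.25). A double bolus is modelled as
#'   two narrow bolus transients: a first pulse that washes through as a
#'   fast intravascular transient (short rise, exponential first-pass
#'   decay) plus the delayed main pulse, which rises over at most half the
#'   inter-bolus delay and then follows the tissue's own washout/retention
#'   kinetics. This gives the characteristic twin inflow peaks separated
#'   by a trough.
#' @param movement_noise_sd_gs Standard deviation of the white noise
#'   component in greyscale units; the sinusoidal oscillation amplitude
#'   defaults to the same value.
#' @param oscillation_amplitude_gs Amplitude of the 0.2-0.5 Hz oscillation;
#'   defaults to `movement_noise_sd_gs`.
#' @param movement_spike `NULL`, or a list with `time_s`, `amplitude_gs`
#'   and `width_s` (Gaussian bump modelling inward camera movement).
#' @param truncation_time_s `NULL`, or the time at which the recording ends.
#' @return An object of class `artifact_config`.
#' @export
artifact_config <- function(saturation_ceiling_gs = 255,
                            enable_saturation = FALSE,
                            saturation_gain = 2.0,
                            double_bolus = NULL,
                            movement_noise_sd_gs = 0,
                            oscillation_amplitude_gs = movement_noise_sd_gs,
                            movement_spike = NULL,
                            truncation_time_s = NULL) {
  if (!is.null(double_bolus)) {
    stopifnot(is.list(double_bolus),
              is.numeric(double_bolus$second_peak_delay_s),
              double_bolus$second_peak_delay_s > 0)
    amp <- double_bolus$second_peak_relative_amplitude
    if (is.null(amp)) amp <- 0.6
    if (amp <= 0 || amp > 1)
      stop("second_peak_relative_amplitude must lie in (0, 1]", call. = FALSE)
    double_bolus$second_peak_relative_amplitude <- amp
    if (is.null(double_bolus$first_pass_rate_per_s))
      double_bolus$first_pass_rate_per_s <- 0.25
  }
  if (movement_noise_sd_gs < 0)
    stop("movement_noise_sd_gs must be >= 0", call. = FALSE)
  structure(
    list(saturation_ceiling_gs = saturation_ceiling_gs,
         enable_saturation = isTRUE(enable_saturation),
         saturation_gain = saturation_gain,
         double_bolus = double_bolus,
         movement_noise_sd_gs = movement_noise_sd_gs,
         oscillation_amplitude_gs = oscillation_amplitude_gs,
         movement_spike = movement_spike,
         truncation_time_s = truncation_time_s),
    class = "artifact_config"
  )
}

#' Generate one synthetic fluorescence trace
#'
#' Samples the noiseless kinetic curve uniformly, then applies artifacts in
#' a fixed, documented order: double bolus -> movement noise and spike ->
#' overdose gain -> truncation -> clip to \[0, ceiling\].
#'
#' @param params A [kinetic_params()] object.
#' @param artifacts An [artifact_config()] object.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_s Recording duration in seconds (must exceed
#'   `onset_time_s + time_to_peak_s`).
#' @param seed Optional integer seed (only needed when artifacts are
#'   stochastic).
#' @param trace_id,patient_id,class_label Metadata carried on the trace.
#' @return A [fluorescence_trace()].
#' @export
generate_trace <- function(params, artifacts = artifact_config(),
                           sampling_rate_hz = 5, duration_s = 300,
                           seed = NULL, trace_id = "trace",
                           patient_id = NA_character_,
                           class_label = "unknown") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(artifacts, "artifact_config"))
  if (sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be > 0", call. = FALSE)
  if (duration_s <= params$onset_time_s + params$time_to_peak_s)
    stop("duration_s must exceed onset_time_s + time_to_peak_s", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  t <- seq(0, duration_s, by = 1 / sampling_rate_hz)
  x <- kinetic_curve(t, params)

  db <- artifacts$double_bolus
  if (!is.null(db)) {
    if (is.null(db$first_pass_rate_per_s)) db$first_pass_rate_per_s <- 0.25
    if (is.null(db$second_peak_relative_amplitude))
      db$second_peak_relative_amplitude <- 0.6
    # both pulses rise like a quick bolus; a rise wider than half the
    # inter-bolus delay would swallow the trough between the peaks
    ttp_bolus <- min(params$time_to_peak_s, db$second_peak_delay_s / 2)
    transient <- params   # first pulse: fast first-pass washout, no retention
    transient$time_to_peak_s <- ttp_bolus
    transient$washout_rate_per_s <- db$first_pass_rate_per_s
    transient$plateau_fraction <- 0
    second <- params      # main pulse: the ROI's own washout/retention tail
    second$onset_time_s <- params$onset_time_s + db$second_peak_delay_s
    second$time_to_peak_s <- ttp_bolus
    second$peak_intensity_gs <- params$peak_intensity_gs *
      db$second_peak_relative_amplitude
    x <- kinetic_curve(t, transient) + kinetic_curve(t, second)
  }

  if (artifacts$movement_noise_sd_gs > 0 ||
      artifacts$oscillation_amplitude_gs > 0) {
    freq <- stats::runif(1, 0.2, 0.5)
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x +
      artifacts$oscillation_amplitude_gs * sin(2 * pi * freq * t + phase) +
      stats::rnorm(length(t), 0, artifacts$movement_noise_sd_gs)
  }

  spike <- artifacts$movement_spike
  if (!is.null(spike)) {
    x <- x + spike$amplitude_gs *
      exp(-(t - spike$time_s)^2 / (2 * spike$width_s^2))
  }

  if (artifacts$enable_saturation) x <- x * artifacts$saturation_gain

  if (!is.null(artifacts$truncation_time_s)) {
    keep <- t <= artifacts$truncation_time_s
    t <- t[keep]; x <- x[keep]
  }

  x <- pmin(pmax(x, 0), artifacts$saturation_ceiling_gs)
  fluorescence_trace(t, x, trace_id = trace_id, patient_id = patient_id,
                     class_label = class_label)
}

#' Trace-duration distributions for cohort generation
#'
#' `duration_distribution()` builds one of:
#' * `"post_peak_quota"` (default): per-trace durations are
#'   `t_peak + offset`, with post-peak offsets drawn from bands so that a
#'   prescribed number of traces ends inside each band. Offsets keep a
#'   guard margin (`margin_s`) away from the band edges so that the
#'   jitter between the analytic peak and the peak detected on the
#'   smoothed noisy curve cannot flip which downslope horizons a trace
#'   reaches. The default quota
#'   reproduces the missingness profile of the emulated clinical cohort: out
#'   of 251 ROIs, 11 end between 100 and 200 s post-peak, a further 61
#'   between 200 and 300 s and a further 34 between 300 and 400 s (so
#'   11/72/106 ROIs lack the 200/300/400-s downslopes), and every trace
#'   retains at least 100 s after its peak. Quotas scale proportionally for
#'   other cohort sizes.
#' * `"fixed"`: every trace has duration `value` seconds.
#' * `"uniform"`: durations drawn uniformly from `[min, max]` seconds.
#' * `"explicit"`: durations given as a vector, recycled in trace order.
#'
#' @param type Distribution type.
#' @param value,min,max,values Type-specific parameters (seconds).
#' @param band_edges Post-peak band edges in seconds (quota type).
#' @param band_counts Number of traces (out of `reference_n`) ending in each
#'   of the first `length(band_counts)` bands; the remainder fall in the
#'   last band.
#' @param reference_n Cohort size the counts refer to.
#' @param margin_s Guard margin (seconds) kept between sampled offsets and
#'   the band edges (quota type).
#' @return An object of class `duration_distribution`.
#' @export
duration_distribution <- function(type = c("post_peak_quota", "fixed",
                                           "uniform", "explicit"),
                                  value = 300, min = 120, max = 900,
                                  values = NULL,
                                  band_edges = c(100, 200, 300, 400, 860),
                                  band_counts = c(11, 61, 34),
                                  reference_n = 251, margin_s = 20) {
  type <- match.arg(type)
  if (type == "explicit" && is.null(values))
    stop("explicit duration distribution needs `values`", call. = FALSE)
  structure(list(type = type, value = value, min = min, max = max,
                 values = values, band_edges = band_edges,
                 band_counts = band_counts, reference_n = reference_n,
                 margin_s = margin_s),
            class = "duration_distribution")
}

draw_durations <- function(dist, n, t_peaks) {
  switch(dist$type,
    fixed = rep(dist$value, n),
    uniform = stats::runif(n, dist$min, dist$max),
    explicit = rep_len(dist$values, n),
    post_peak_quota = {
      counts <- round(dist$band_counts * n / dist$reference_n)
      counts <- pmin(counts, n)
      n_bands <- length(dist$band_edges) - 1
      band_of <- rep(n_bands, n)  # default: last (longest) band
      short_idx <- sample.int(n, min(sum(counts), n))
      pos <- 1
      for (b in seq_along(counts)) {
        take <- counts[b]
        if (take > 0 && pos <= length(short_idx)) {
          idx <- short_idx[pos:min(pos + take - 1, length(short_idx))]
          band_of[idx] <- b
          pos <- pos + take
        }
      }
      lo <- dist$band_edges[band_of] + dist$margin_s
      hi <- pmax(dist$band_edges[band_of + 1] - dist$margin_s, lo + 1)
      t_peaks + stats::runif(n, lo, hi)
    })
}

#' Synthetic-cohort configuration
#'
#' Full parameterization of the cohort generator: class composition,
#' per-class kinetic presets, artifact occurrence rates, sampling, the
#' trace-duration distribution and the seed. Defaults emulate a rectal
#' neoplasia cohort of 37 patients (13 with benign, 24 with malignant
#' lesions) contributing 251 ROIs in total: healthy control ROIs from every
#' patient plus lesion ROIs of the patient's lesion class.
#'
#' @param n_patients Number of patients.
#' @param rois_per_class Named total ROI counts for classes
#'   healthy/benign/cancer (classes with 0 are omitted).
#' @param patient_lesion_split Named counts of benign and cancer patients
#'   (must sum to `n_patients`).
#' @param presets Per-class kinetic presets, see [class_presets()].
#' @param artifacts Baseline [artifact_config()] for every trace.
#' @param p_double_bolus,p_saturation,p_spike Per-trace occurrence
#'   probabilities of the corresponding artifacts. The default cohort has
#'   no camera-lurch spikes (`p_spike = 0`): it emulates acquisition with
#'   a steadied camera where residual motion shows up as the oscillatory
#'   noise component; set `p_spike > 0` to study gross-movement artifacts.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param durations A [duration_distribution()].
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 37,
                          rois_per_class = c(healthy = 88, benign = 46,
                                             cancer = 117),
                          patient_lesion_split = c(benign = 13, cancer = 24),
                          presets = class_presets(),
                          artifacts = artifact_config(movement_noise_sd_gs = 3),
                          p_double_bolus = 1 / 37,
                          p_saturation = 0,
                          p_spike = 0,
                          sampling_rate_hz = 5,
                          durations = duration_distribution(),
                          seed = 1) {
  rois_per_class <- rois_per_class[rois_per_class > 0]
  if (length(rois_per_class) == 0)
    stop("at least one class must have a positive ROI count", call. = FALSE)
  if (any(!names(rois_per_class) %in% c("healthy", "benign", "cancer")))
    stop("rois_per_class names must be healthy/benign/cancer", call. = FALSE)
  if (sum(patient_lesion_split) != n_patients)
    stop("patient_lesion_split must sum to n_patients", call. = FALSE)
  structure(
    list(n_patients = n_patients, rois_per_class = rois_per_class,
         patient_lesion_split = patient_lesion_split, presets = presets,
         artifacts = artifacts, p_double_bolus = p_double_bolus,
         p_saturation = p_saturation, p_spike = p_spike,
         sampling_rate_hz = sampling_rate_hz, durations = durations,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

draw_params <- function(preset) {
  m <- preset$mean
  cv <- preset$cv
  draw <- function(mu, lo, hi) {
    val <- stats::rnorm(1, mu, cv * mu)
    min(max(val, lo), hi)
  }
  kinetic_params(
    onset_time_s = draw(m$onset_time_s, 0.5, 30),
    time_to_peak_s = draw(m$time_to_peak_s, 3, 60),
    peak_intensity_gs = draw(m$peak_intensity_gs, 20, 255),
    washout_rate_per_s = draw(m$washout_rate_per_s, 0, 1),
    plateau_fraction = if (m$plateau_fraction == 0) 0 else
      draw(m$plateau_fraction, 0, 0.95)
  )
}

#' Generate a synthetic cohort of fluorescence traces
#'
#' Draws per-ROI kinetic parameters from the per-class presets, assigns ROIs
#' to patients (healthy control ROIs across all patients; lesion ROIs to
#' patients with that lesion class), applies artifacts with the configured
#' occurrence probabilities, and draws per-trace durations so that a known
#' subset of traces is interrupted before the longer downslope horizons.
#'
#' @param config A [cohort_config()].
#' @return A list with `traces` (list of [fluorescence_trace()]) and
#'   `manifest` (data frame of ground truth: class, patient, true kinetic
#'   parameters, artifact flags, duration, analytic milestone values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  classes <- names(config$rois_per_class)
  n_total <- sum(config$rois_per_class)

  # patient pools: lesion ROIs go to patients carrying that lesion class
  pt_ids <- sprintf("P%02d", seq_len(config$n_patients))
  lesion_of_patient <- rep(names(config$patient_lesion_split),
                           config$patient_lesion_split)
  pools <- list(
    healthy = pt_ids,
    benign = pt_ids[lesion_of_patient == "benign"],
    cancer = pt_ids[lesion_of_patient == "cancer"]
  )

  cls_vec <- rep(classes, config$rois_per_class)
  patient_vec <- character(n_total)
  for (cls in classes) {
    idx <- which(cls_vec == cls)
    pool <- pools[[cls]]
    if (length(pool) == 0)
      stop(sprintf("no patients available for class %s", cls), call. = FALSE)
    patient_vec[idx] <- rep_len(pool, length(idx))
  }

  params_list <- lapply(cls_vec, function(cls) draw_params(config$presets[[cls]]))
  t_peaks <- vapply(params_list, analytic_tmax, numeric(1))

  has_db <- stats::runif(n_total) < config$p_double_bolus
  has_sat <- stats::runif(n_total) < config$p_saturation
  has_spike <- stats::runif(n_total) < config$p_spike
  db_delay <- stats::runif(n_total, 8, 12)
  db_amp <- stats::runif(n_total, 0.4, 0.8)

  # downslope horizons count from the *first detected* peak; for a double
  # bolus that is the first pulse, which peaks after the short bolus rise
  t_first_peak <- ifelse(
    has_db,
    vapply(seq_len(n_total), function(i)
      params_list[[i]]$onset_time_s +
        min(params_list[[i]]$time_to_peak_s, db_delay[i] / 2), numeric(1)),
    t_peaks)
  durations <- draw_durations(config$durations, n_total, t_first_peak)
  durations <- pmax(durations, t_peaks + 15)  # guard: peak must be recorded

  trace_seeds <- sample.int(.Machine$integer.max - 1, n_total)

  traces <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    art <- config$artifacts
    art$enable_saturation <- has_sat[i]
    if (has_db[i]) {
      art$double_bolus <- list(second_peak_delay_s = db_delay[i],
                               second_peak_relative_amplitude = db_amp[i])
    }
    if (has_spike[i]) {
      art$movement_spike <- list(
        time_s = stats::runif(1, t_peaks[i] + 20,
                              max(durations[i] - 5, t_peaks[i] + 25)),
        amplitude_gs = stats::runif(1, 5, 20),
        width_s = stats::runif(1, 1, 3))
    }
    traces[[i]] <- generate_trace(
      params_list[[i]], art,
      sampling_rate_hz = config$sampling_rate_hz,
      duration_s = durations[i], seed = trace_seeds[i],
      trace_id = sprintf("ROI%03d", i), patient_id = patient_vec[i],
      class_label = cls_vec[i])
  }

  manifest <- data.frame(
    trace_id = sprintf("ROI%03d", seq_len(n_total)),
    patient_id = patient_vec,
    class = cls_vec,
    duration_s = durations,
    onset_time_s = vapply(params_list, `[[`, numeric(1), "onset_time_s"),
    time_to_peak_s = vapply(params_list, `[[`, numeric(1), "time_to_peak_s"),
    peak_intensity_gs = vapply(params_list, `[[`, numeric(1),
                               "peak_intensity_gs"),
    washout_rate_per_s = vapply(params_list, `[[`, numeric(1),
                                "washout_rate_per_s"),
    plateau_fraction = vapply(params_list, `[[`, numeric(1),
                              "plateau_fraction"),
    t_peak_s = t_first_peak,
    double_bolus = has_db,
    saturated = has_sat,
    movement_spike = has_spike,
    stringsAsFactors = FALSE
  )
  for (N in c(10, 50, 100, 200, 300, 400)) {
    manifest[[paste0("true_ds", N)]] <-
      vapply(params_list, analytic_downslope, numeric(1), horizon_s = N)
  }

  list(traces = traces, manifest = manifest)
}

#' Render a greyscale frame stack from traces
#'
#' Builds a synthetic image sequence in which each ROI box carries one
#' trace: pixels inside a box at frame j are drawn from
#' Normal(trace value at that frame time, `pixel_noise_sd`), the background
#' is low-intensity noise, and every pixel is clipped to \[0, 255\]. All
#' traces must share the same time grid. Used to exercise the trace
#' extraction path end to end.
#'
#' @param traces List of [fluorescence_trace()] with identical `time_s`.
#' @param roi_boxes Data frame with columns `roi_id, x0, y0, width, height`
#'   (0-based pixel origin, half-open boxes); boxes must be disjoint and
#'   inside the frame.
#' @param frame_shape `c(height, width)` in pixels.
#' @param pixel_noise_sd Pixel noise SD in greyscale units (0 for exact
#'   round trips).
#' @param background_mean,background_sd Background intensity model.
#' @param seed Optional integer seed.
#' @return A list with `frames` (array height x width x n_frames),
#'   `time_s`, and `roi_boxes`.
#' @export
render_frame_stack <- function(traces, roi_boxes, frame_shape = c(48, 64),
                               pixel_noise_sd = 0, background_mean = 5,
                               background_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(traces) == nrow(roi_boxes))
  time_s <- traces[[1]]$time_s
  for (tr in traces)
    if (!isTRUE(all.equal(tr$time_s, time_s)))
      stop("all traces must share the same time grid", call. = FALSE)
  validate_roi_boxes(roi_boxes, frame_shape)

  H <- frame_shape[1]; W <- frame_shape[2]; n_frames <- length(time_s)
  frames <- array(stats::rnorm(H * W * n_frames, background_mean,
                               background_sd),
                  dim = c(H, W, n_frames))
  for (r in seq_len(nrow(roi_boxes))) {
    rows <- (roi_boxes$y0[r] + 1):(roi_boxes$y0[r] + roi_boxes$height[r])
    cols <- (roi_boxes$x0[r] + 1):(roi_boxes$x0[r] + roi_boxes$width[r])
    npix <- length(rows) * length(cols)
    vals <- traces[[r]]$intensity
    for (j in seq_len(n_frames)) {
      box <- if (pixel_noise_sd > 0)
        stats::rnorm(npix, vals[j], pixel_noise_sd) else rep(vals[j], npix)
      frames[rows, cols, j] <- box
    }
  }
  frames <- pmin(pmax(frames, 0), 255)
  list(frames = frames, time_s = time_s, roi_boxes = roi_boxes)
}

validate_roi_boxes <- function(roi_boxes, frame_shape) {
  need <- c("roi_id", "x0", "y0", "width", "height")
  if (!all(need %in% names(roi_boxes)))
    stop("roi_boxes needs columns roi_id, x0, y0, width, height",
         call. = FALSE)
  H <- frame_shape[1]; W <- frame_shape[2]
  if (any(roi_boxes$width < 1) || any(roi_boxes$height < 1))
    stop("ROI boxes must have width and height >= 1", call. = FALSE)
  if (any(roi_boxes$x0 < 0) || any(roi_boxes$y0 < 0) ||
      any(roi_boxes$x0 + roi_boxes$width > W) ||
      any(roi_boxes$y0 + roi_boxes$height > H)) {
    bad <- which(roi_boxes$x0 < 0 | roi_boxes$y0 < 0 |
                 roi_boxes$x0 + roi_boxes$width > W |
                 roi_boxes$y0 + roi_boxes$height > H)[1]
    stop(sprintf("ROI box %s out of frame bounds", roi_boxes$roi_id[bad]),
         call. = FALSE)
  }
  n <- nrow(roi_boxes)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      overlap_x <- roi_boxes$x0[i] < roi_boxes$x0[j] + roi_boxes$width[j] &&
        roi_boxes$x0[j] < roi_boxes$x0[i] + roi_boxes$width[i]
      overlap_y <- roi_boxes$y0[i] < roi_boxes$y0[j] + roi_boxes$height[j] &&
        roi_boxes$y0[j] < roi_boxes$y0[i] + roi_boxes$height[i]
      if (overlap_x && overlap_y)
        stop(sprintf("ROI boxes %s and %s overlap", roi_boxes$roi_id[i],
                     roi_boxes$roi_id[j]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
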