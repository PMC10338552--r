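#' Locate local maxima with topographic prominence
#'
#' Finds interior local maxima (flat-topped peaks count once, positioned at
#' the first sample of the flat run) and computes each peak's topographic
#' prominence: the drop from the peak to the higher of the two lowest
#' points separating it from higher terrain (or from the series ends).
#'
#' @param x Numeric vector.
#' @return A data frame with columns `index`, `height`, `prominence`,
#'   ordered by index. Zero rows when no interior local maximum exists.
#' @export
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3)
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  # runs of equal values; a peak run has lower values on both sides
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peak_idx <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
        peak_idx <- c(peak_idx, starts[j])
    }
  }
  if (length(peak_idx) == 0)
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  prom <- vapply(peak_idx, function(i) {
    h <- x[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1 && x[j] <= h) { left_min <- min(left_min, x[j]); j <- j - 1L }
    right_min <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { right_min <- min(right_min, x[j]); j <- j + 1L }
    h - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = peak_idx, height = x[peak_idx], prominence = prom)
}

#' Prominent peaks via hysteresis pruning
#'
#' Single-pass alternation algorithm: a peak is confirmed once the series
#' has risen by at least `threshold` before it and falls by at least
#' `threshold` after it without first exceeding it, which selects exactly
#' the local maxima of topographic prominence >= `threshold`. Linear time,
#' unlike the exhaustive scan in [find_peaks()], which serves as its
#' brute-force oracle.
#'
#' @param x Numeric vector.
#' @param threshold Minimum prominence (same units as `x`).
#' @return Integer indices of the prominent peaks, in order.
#' @export
prominent_peaks <- function(x, threshold) {
  n <- length(x)
  peaks <- integer(0)
  cur_max <- x[1]; cur_max_i <- 1L
  cur_min <- x[1]
  # start descending: a first peak only counts after rising >= threshold
  # above the running minimum, mirroring its topographic left base
  going_up <- FALSE
  for (i in 2:n) {
    xi <- x[i]
    if (going_up) {
      if (xi > cur_max) {
        cur_max <- xi; cur_max_i <- i
      } else if (cur_max - xi >= threshold) {
        # boundary maxima (index 1) are not local peaks
        if (cur_max_i > 1L) peaks <- c(peaks, cur_max_i)
        going_up <- FALSE
        cur_min <- xi
      }
    } else {
      if (xi < cur_min) {
        cur_min <- xi
      } else if (xi - cur_min >= threshold) {
        going_up <- TRUE
        cur_max <- xi; cur_max_i <- i
      }
    }
  }
  peaks
}

#' Detect a detector-saturation plateau
#'
#' Flags a trace as saturated when a run of consecutive samples at or above
#' the greyscale ceiling lasts at least `min_run_s` seconds — the
#' persistent-plateau artifact caused by excessive ICG dosing, which
#' destroys curve shape and should exclude the trace from kinetic analysis.
#'
#' @param trace A [fluorescence_trace()] in greyscale units.
#' @param ceiling_gs Saturation ceiling (default 254, i.e. "at the top of
#'   the 8-bit scale").
#' @param min_run_s Minimum run duration (seconds) to count as a plateau.
#' @return A list with `saturated` (flag) and `saturated_span_s` (duration
#'   of the longest qualifying run, 0 when none).
#' @export
detect_saturation <- function(trace, ceiling_gs = 254, min_run_s = 2) {
  fs <- trace$sampling_rate_hz
  at_ceiling <- trace$intensity >= ceiling_gs
  r <- rle(at_ceiling)
  spans <- (r$lengths[r$values] - 1) / fs
  spans <- spans[spans >= min_run_s]
  list(saturated = length(spans) > 0,
       saturated_span_s = if (length(spans) > 0) max(spans) else 0)
}

#' Detect double-bolus twin peaks
#'
#' Flags traces whose inflow shows two or more prominent peaks — the
#' signature of ICG pushed in two pulses, which confounds single-peak
#' milestone extraction. A peak counts if its topographic prominence is at
#' least `prominence_frac` of the trace's global maximum.
#'
#' @param trace A [fluorescence_trace()] (smoothing first is recommended so
#'   noise does not masquerade as peaks).
#' @param prominence_frac Prominence threshold as a fraction of the global
#'   maximum.
#' @param window_s Restrict the search to `time_s <= window_s` (default:
#'   whole trace).
#' @return A list with `double_peak` (flag) and `peak_times_s` (times of
#'   all qualifying peaks).
#' @export
detect_double_peak <- function(trace, prominence_frac = 0.15,
                               window_s = NULL) {
  x <- trace$intensity
  t <- trace$time_s
  if (!is.null(window_s)) {
    keep <- t <= window_s
    x <- x[keep]; t <- t[keep]
  }
  idx <- prominent_peaks(x, prominence_frac * max(x))
  list(double_peak = length(idx) >= 2, peak_times_s = t[idx])
}

#' Savitzky-Golay smoothing of a trace
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial fit) to
#' the intensity series to suppress movement oscillation and white noise
#' while preserving peak shape, which is what makes automated peak detection
#' reliable. The window is specified in seconds and converted to an odd
#' number of samples at the trace's sampling rate.
#'
#' @param trace A [fluorescence_trace()] (raw or normalized).
#' @param window_s Filter window length in seconds.
#' @param polyorder Polynomial order (must be < window length in samples).
#' @return A trace of the same class with filtered intensities, clipped to
#'   the valid intensity range.
#' @export
smooth_trace <- function(trace, window_s = 11, polyorder = 3) {
  fs <- trace$sampling_rate_hz
  n <- max(round(window_s * fs), polyorder + 2)
  if (n %% 2 == 0) n <- n + 1
  if (length(trace$intensity) < n)
    stop(sprintf(
      "trace has %d samples but the %g s window needs %d; use a smaller window_s",
      length(trace$intensity), window_s, n), call. = FALSE)
  y <- signal::sgolayfilt(trace$intensity, p = polyorder, n = n)
  hi <- if (is_normalized(trace)) 1 else 255
  trace$intensity <- pmin(pmax(y, 0), hi)
  trace
}

#' Peak-normalize a trace
#'
#' Divides every intensity sample by the curve's peak (maximum) intensity
#' reading, mapping the trace onto \[0, 1\]. Normalization removes the
#' absolute-intensity differences caused by camera-to-tissue distance, so
#' that slope-based curve milestones become comparable across ROIs imaged
#' at different distances.
#'
#' @param trace A [fluorescence_trace()].
#' @return A `normalized_trace` whose maximum is exactly 1; the divisor is
#'   stored as `normalization_peak_gs`.
#' @export
normalize_trace <- function(trace) {
  m <- max(trace$intensity)
  if (m <= 0)
    stop("trace has no positive intensity; cannot normalize", call. = FALSE)
  new_normalized_trace(trace, trace$intensity / m, m)
}

#' Standard conditioning pipeline for one trace
#'
#' Smooths the raw greyscale trace (so noise spikes do not set the
#' normalization divisor), then peak-normalizes it.
#'
#' @inheritParams smooth_trace
#' @return A `normalized_trace`.
#' @export
preprocess_trace <- function(trace, window_s = 11, polyorder = 3) {
  normalize_trace(smooth_trace(trace, window_s = window_s,
                               polyorder = polyorder))
}

#' Quality-control report for a cohort of traces
#'
#' Runs saturation and double-peak detection on every trace (double-peak
#' detection on the smoothed curve) and reports the usable post-peak
#' duration.
#'
#' @param traces List of [fluorescence_trace()].
#' @param ceiling_gs,min_run_s Saturation detection parameters, see
#'   [detect_saturation()].
#' @param prominence_frac Double-peak prominence threshold, see
#'   [detect_double_peak()].
#' @param window_s Smoothing window (seconds) used for peak localisation.
#' @param dp_window_s Shorter smoothing window used before double-peak
#'   detection; must stay below the twin-peak separation (about 10 s for
#'   double boluses) or the filter merges the peaks.
#' @return A data frame with one row per trace: `trace_id`, `saturated`,
#'   `saturated_span_s`, `double_peak`, `peak_times_s` (semicolon-joined),
#'   `max_intensity_gs`, `usable_post_peak_s`.
#' @export
qc_report <- function(traces, ceiling_gs = 254, min_run_s = 2,
                      prominence_frac = 0.15, window_s = 11,
                      dp_window_s = 3) {
  rows <- lapply(traces, function(tr) {
    sat <- detect_saturation(tr, ceiling_gs = ceiling_gs,
                             min_run_s = min_run_s)
    sm <- smooth_trace(tr, window_s = window_s)
    dp <- detect_double_peak(smooth_trace(tr, window_s = dp_window_s),
                             prominence_frac = prominence_frac)
    peak_t <- sm$time_s[which.max(sm$intensity)]
    data.frame(
      trace_id = tr$trace_id,
      saturated = sat$saturated,
      saturated_span_s = sat$saturated_span_s,
      double_peak = dp$double_peak,
      peak_times_s = paste(round(dp$peak_times_s, 2), collapse = ";"),
      max_intensity_gs = max(tr$intensity),
      usable_post_peak_s = max(tr$time_s) - peak_t,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
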