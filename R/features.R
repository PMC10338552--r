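#' Detect the first prominent peak of a normalized trace
#'
#' Returns the earliest local maximum whose topographic prominence is at
#' least `prominence_frac` of the global maximum, so that a double-bolus
#' curve reports its *first* inflow peak rather than the taller of the two.
#' When no interior local maximum meets the threshold, the global argmax is
#' used (earliest sample on ties); a trace that is still rising at its last
#' sample has not reached its peak and raises an error.
#'
#' @param trace A smoothed, normalized trace (raw traces are accepted; the
#'   prominence threshold is relative, so units do not matter).
#' @param prominence_frac Prominence threshold as a fraction of the global
#'   maximum.
#' @return A list with `index`, `time_s` and `value` of the detected peak.
#' @export
detect_first_peak <- function(trace, prominence_frac = 0.15) {
  x <- trace$intensity
  n <- length(x)
  idx <- prominent_peaks(x, prominence_frac * max(x))
  if (length(idx) > 0) {
    i <- idx[1]
  } else {
    i <- which.max(x)
    if (i == n)
      stop("peak not reached: trace is still rising at its last sample",
           call. = FALSE)
  }
  list(index = i, time_s = trace$time_s[i], value = x[i])
}

interp_at <- function(time_s, x, t) {
  stats::approx(time_s, x, xout = t, rule = 1)$y
}

#' Extract curve-milestone features from a normalized trace
#'
#' Computes the fixed milestone vector describing ICG inflow/outflow
#' kinetics:
#' * `ttfp_s` — time to first peak (Tmax);
#' * `t_half_s` — first crossing of half-maximal intensity on the rise,
#'   linearly interpolated between samples;
#' * `time_ratio` — `t_half_s / ttfp_s`;
#' * `upslope` — least-squares slope of the normalized rise between the
#'   first crossing of 0.1 and the peak (per second);
#' * `ds10 ... ds400` — normalized downslopes
#'   \eqn{(F(t_{peak}+N) - F(t_{peak}))/N} at horizons N seconds after the
#'   peak, with \eqn{F(t_{peak}+N)} linearly interpolated; horizons beyond
#'   the end of the trace are `NA` (missing — extrapolation is the
#'   imputation module's job);
#' * `kurtosis` — Fisher excess kurtosis of the full normalized series.
#'
#' @param trace A smoothed, normalized trace.
#' @param horizons_s Downslope horizons in seconds after the peak.
#' @param prominence_frac Passed to [detect_first_peak()].
#' @return An object of class `milestone_features`: a named list of the
#'   milestone values plus a `provenance` character vector
#'   (observed/missing) for the downslope fields and the `peak` detection
#'   result.
#' @export
extract_milestones <- function(trace,
                               horizons_s = c(10, 50, 100, 200, 300, 400),
                               prominence_frac = 0.15) {
  peak <- detect_first_peak(trace, prominence_frac = prominence_frac)
  x <- trace$intensity
  t <- trace$time_s
  v_peak <- peak$value

  # first crossing of half the peak value on the rise
  half <- 0.5 * v_peak
  i_half <- which(x >= half)[1]
  t_half <- if (i_half == 1) t[1] else {
    t0 <- t[i_half - 1]; t1 <- t[i_half]
    x0 <- x[i_half - 1]; x1 <- x[i_half]
    t0 + (half - x0) / (x1 - x0) * (t1 - t0)
  }

  # upslope: LS slope between first crossing of 0.1 * peak and the peak
  i_start <- which(x >= 0.1 * v_peak)[1]
  upslope <- if (peak$index - i_start >= 1) {
    tt <- t[i_start:peak$index]; xx <- x[i_start:peak$index]
    sum((tt - mean(tt)) * (xx - mean(xx))) / sum((tt - mean(tt))^2)
  } else NA_real_

  ds <- numeric(length(horizons_s))
  prov <- character(length(horizons_s))
  names(ds) <- names(prov) <- paste0("ds", horizons_s)
  for (h in seq_along(horizons_s)) {
    target <- peak$time_s + horizons_s[h]
    if (target > t[length(t)]) {
      ds[h] <- NA_real_
      prov[h] <- "missing"
    } else {
      ds[h] <- (interp_at(t, x, target) - v_peak) / horizons_s[h]
      prov[h] <- "observed"
    }
  }

  structure(
    c(list(trace_id = trace$trace_id,
           ttfp_s = peak$time_s,
           t_half_s = t_half,
           time_ratio = t_half / peak$time_s,
           upslope = upslope),
      as.list(ds),
      list(kurtosis = e1071::kurtosis(x, type = 1),
           provenance = prov,
           peak = peak)),
    class = "milestone_features"
  )
}

#' Build the cohort feature table
#'
#' Runs the standard conditioning pipeline (smooth then normalize) and
#' milestone extraction on every trace, returning one row per ROI with
#' explicit `NA` for downslope horizons the recording did not reach, plus a
#' per-horizon missingness summary.
#'
#' @param traces List of [fluorescence_trace()] with unique `trace_id`s.
#' @param horizons_s Downslope horizons in seconds.
#' @param window_s,polyorder Smoothing parameters, see [smooth_trace()].
#' @param preprocess Set to `FALSE` when `traces` are already smoothed and
#'   normalized.
#' @param prominence_frac Passed to [detect_first_peak()].
#' @return A data frame with columns `trace_id, patient_id, class, ttfp_s,
#'   t_half_s, time_ratio, upslope, ds10 ... ds400, kurtosis` and matching
#'   `ds*_provenance` columns; the attribute `"missingness"` holds a named
#'   count of ROIs missing each horizon.
#' @export
build_feature_table <- function(traces,
                                horizons_s = c(10, 50, 100, 200, 300, 400),
                                window_s = 11, polyorder = 3,
                                preprocess = TRUE,
                                prominence_frac = 0.15) {
  if (length(traces) == 0) stop("empty cohort", call. = FALSE)
  ids <- vapply(traces, `[[`, character(1), "trace_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate trace_id: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  rows <- lapply(traces, function(tr) {
    nt <- if (preprocess)
      preprocess_trace(tr, window_s = window_s, polyorder = polyorder)
    else tr
    ms <- extract_milestones(nt, horizons_s = horizons_s,
                             prominence_frac = prominence_frac)
    row <- data.frame(
      trace_id = tr$trace_id, patient_id = tr$patient_id,
      class = tr$class_label,
      ttfp_s = ms$ttfp_s, t_half_s = ms$t_half_s,
      time_ratio = ms$time_ratio, upslope = ms$upslope,
      stringsAsFactors = FALSE)
    for (h in horizons_s) row[[paste0("ds", h)]] <- ms[[paste0("ds", h)]]
    row$kurtosis <- ms$kurtosis
    for (h in horizons_s)
      row[[paste0("ds", h, "_provenance")]] <- ms$provenance[[paste0("ds", h)]]
    row
  })
  out <- do.call(rbind, rows)
  miss <- vapply(horizons_s, function(h) sum(is.na(out[[paste0("ds", h)]])),
                 integer(1))
  names(miss) <- paste0("ds", horizons_s)
  attr(out, "missingness") <- miss
  out
}

#' Per-horizon missingness summary of a feature table
#'
#' @param feature_table Output of [build_feature_table()].
#' @return Named integer vector of ROIs missing each downslope horizon.
#' @export
missingness_summary <- function(feature_table) {
  ds_cols <- grep("^ds[0-9]+$", names(feature_table), value = TRUE)
  vapply(feature_table[ds_cols], function(col) sum(is.na(col)), integer(1))
}
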