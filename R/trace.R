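#' Construct a fluorescence trace
#'
#' A fluorescence trace is one region of interest's (ROI) mean greyscale
#' intensity sampled over time after an intravenous indocyanine green (ICG)
#' bolus, together with patient and lesion metadata. Intensities are detector
#' greyscale units in \[0, 255\]; time is seconds from recording start.
#'
#' @param time_s Numeric vector of strictly increasing sample times (seconds).
#' @param intensity_gs Numeric vector of greyscale intensities in \[0, 255\],
#'   same length as `time_s`.
#' @param trace_id,patient_id Identifiers.
#' @param class_label One of `"healthy"`, `"benign"`, `"cancer"` or
#'   `"unknown"`.
#' @return An object of class `fluorescence_trace`: a list with fields
#'   `time_s`, `intensity`, `trace_id`, `patient_id`, `class_label`,
#'   `sampling_rate_hz` (derived from the median sampling interval) and
#'   `units = "greyscale"`.
#' @export
fluorescence_trace <- function(time_s, intensity_gs, trace_id = "trace",
                               patient_id = NA_character_,
                               class_label = "unknown") {
  validate_trace_vectors(time_s, intensity_gs, max_intensity = 255)
  class_label <- match.arg(class_label,
                           c("healthy", "benign", "cancer", "unknown"))
  structure(
    list(
      time_s = as.numeric(time_s),
      intensity = as.numeric(intensity_gs),
      trace_id = as.character(trace_id),
      patient_id = as.character(patient_id),
      class_label = class_label,
      sampling_rate_hz = 1 / stats::median(diff(time_s)),
      units = "greyscale"
    ),
    class = "fluorescence_trace"
  )
}

validate_trace_vectors <- function(time_s, intensity, max_intensity = 255) {
  if (!is.numeric(time_s) || !is.numeric(intensity))
    stop("time_s and intensity must be numeric", call. = FALSE)
  if (length(time_s) != length(intensity))
    stop("time_s and intensity must have the same length", call. = FALSE)
  if (length(time_s) < 2)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (anyNA(time_s) || any(!is.finite(time_s)))
    stop("time_s contains non-finite values", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity contains non-finite values", call. = FALSE)
  if (any(diff(time_s) <= 0)) {
    row <- which(diff(time_s) <= 0)[1] + 1L
    stop(sprintf("time_s must be strictly increasing (violated at row %d)", row),
         call. = FALSE)
  }
  if (any(intensity < 0) || any(intensity > max_intensity))
    stop(sprintf("intensity must lie in [0, %s]", format(max_intensity)),
         call. = FALSE)
  invisible(TRUE)
}

new_normalized_trace <- function(trace, intensity, peak_gs) {
  out <- trace
  out$intensity <- intensity
  out$normalization_peak_gs <- peak_gs
  out$units <- "normalized"
  class(out) <- c("normalized_trace", "fluorescence_trace")
  out
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<%s> %s  patient=%s  class=%s\n",
              paste(class(x), collapse = "/"), x$trace_id, x$patient_id,
              x$class_label))
  cat(sprintf("  %d samples over %.1f s at %.2f Hz, intensity range [%.3f, %.3f] (%s)\n",
              length(x$time_s), max(x$time_s) - min(x$time_s),
              x$sampling_rate_hz, min(x$intensity), max(x$intensity), x$units))
  invisible(x)
}

#' Coerce a trace to a data frame
#'
#' @param x A `fluorescence_trace`.
#' @param ... Unused.
#' @return A data frame with columns `time_s` and `intensity_gs` (raw traces)
#'   or `intensity` (normalized traces).
#' @export
as.data.frame.fluorescence_trace <- function(x, ...) {
  if (identical(x$units, "normalized"))
    data.frame(time_s = x$time_s, intensity = x$intensity)
  else
    data.frame(time_s = x$time_s, intensity_gs = x$intensity)
}

is_normalized <- function(trace) inherits(trace, "normalized_trace")

#' Truncate a trace in time
#'
#' Keeps samples with `time_s <= t_max_s`. Used to emulate early video
#' termination and to build truncated tails for imputation experiments.
#'
#' @param trace A `fluorescence_trace`.
#' @param t_max_s Last time (seconds) to keep.
#' @return The truncated trace (same class).
#' @export
truncate_trace <- function(trace, t_max_s) {
  keep <- trace$time_s <= t_max_s
  if (sum(keep) < 2)
    stop("truncation would leave fewer than 2 samples", call. = FALSE)
  trace$time_s <- trace$time_s[keep]
  trace$intensity <- trace$intensity[keep]
  trace
}
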