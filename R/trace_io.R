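#' Extract mean-intensity traces from a greyscale frame stack
#'
#' The "digital biopsy" sampling step: for every box ROI, each time sample is
#' the arithmetic mean of the pixel greyscale values inside the box at that
#' frame (median available via `statistic`). Boxes are static in frame
#' coordinates; no motion tracking is performed.
#'
#' @param frames Numeric array `height x width x n_frames` of greyscale
#'   values in \[0, 255\] (RGB input is rejected, not converted).
#' @param roi_boxes Data frame with columns `roi_id, x0, y0, width, height`
#'   (0-based origin, half-open), all boxes inside the frame.
#' @param time_s Frame timestamps in seconds (length `n_frames`).
#' @param statistic Pixel aggregator, `"mean"` (default) or `"median"`.
#' @return A list of [fluorescence_trace()], one per ROI, in box order.
#' @export
extract_traces <- function(frames, roi_boxes, time_s,
                           statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (!is.array(frames) || length(dim(frames)) != 3) {
    if (is.array(frames) && length(dim(frames)) == 4)
      stop("RGB/multichannel stacks are not supported; supply a greyscale array",
           call. = FALSE)
    stop("frames must be a 3-d array (height x width x n_frames)",
         call. = FALSE)
  }
  if (dim(frames)[3] < 1) stop("frame stack is empty", call. = FALSE)
  if (length(time_s) != dim(frames)[3])
    stop("time_s must have one timestamp per frame", call. = FALSE)
  validate_roi_boxes(roi_boxes, dim(frames)[1:2])

  agg <- if (statistic == "mean") mean else stats::median
  lapply(seq_len(nrow(roi_boxes)), function(r) {
    rows <- (roi_boxes$y0[r] + 1):(roi_boxes$y0[r] + roi_boxes$height[r])
    cols <- (roi_boxes$x0[r] + 1):(roi_boxes$x0[r] + roi_boxes$width[r])
    vals <- apply(frames[rows, cols, , drop = FALSE], 3, agg)
    fluorescence_trace(time_s, vals,
                       trace_id = as.character(roi_boxes$roi_id[r]))
  })
}

#' Read and write ROI trace CSV files
#'
#' Traces are exchanged as CSV with columns `time_s` and `intensity_gs`
#' (greyscale units, 0-255). `write_trace_csv()` followed by
#' `read_trace_csv()` is the identity to 6 decimal places.
#'
#' @param path File path.
#' @param trace_id,patient_id,class_label Metadata attached on read.
#' @return `read_trace_csv()` returns a [fluorescence_trace()];
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path, trace_id = NULL,
                           patient_id = NA_character_,
                           class_label = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity_gs")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("%s: non-numeric value in column %s at row %d",
                   path, col, bad), call. = FALSE)
    }
  }
  if (any(diff(df$time_s) <= 0)) {
    row <- which(diff(df$time_s) <= 0)[1] + 1L
    stop(sprintf("%s: time_s not strictly increasing at row %d", path, row),
         call. = FALSE)
  }
  if (is.null(trace_id))
    trace_id <- sub("\\.csv$", "", basename(path))
  fluorescence_trace(df$time_s, df$intensity_gs, trace_id = trace_id,
                     patient_id = patient_id, class_label = class_label)
}

#' @rdname read_trace_csv
#' @param trace A [fluorescence_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = round(trace$time_s, 6),
                   intensity_gs = round(trace$intensity, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write ROI box definition CSV files
#'
#' ROI boxes use 0-based, half-open pixel coordinates with columns
#' `roi_id, x0, y0, width, height`.
#'
#' @param path File path.
#' @return `read_roi_csv()` returns the box data frame.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "x0", "y0", "width", "height")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname read_roi_csv
#' @param roi_boxes ROI box data frame.
#' @export
write_roi_csv <- function(roi_boxes, path) {
  utils::write.csv(roi_boxes, path, row.names = FALSE)
  invisible(path)
}

#' Read and write greyscale frame stacks as multi-page TIFF
#'
#' Frames are stored as 8-bit greyscale pages, so intensities are quantized
#' to integer greyscale units on write; a `<stem>_times.csv` sidecar holds
#' the frame timestamps.
#'
#' @param frames Array `height x width x n_frames`, values in \[0, 255\].
#' @param time_s Frame timestamps (seconds).
#' @param path TIFF file path.
#' @return `read_frame_stack_tiff()` returns `list(frames, time_s)`.
#' @export
write_frame_stack_tiff <- function(frames, time_s, path) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(time_s))
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(j) frames[, , j] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  utils::write.csv(data.frame(frame = seq_along(time_s), time_s = time_s),
                   times_sidecar(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_stack_tiff
#' @export
read_frame_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3)
    stop("RGB/multichannel TIFF is not supported; supply greyscale pages",
         call. = FALSE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (j in seq_along(pages)) frames[, , j] <- pages[[j]] * 255
  tfile <- times_sidecar(path)
  time_s <- if (file.exists(tfile))
    utils::read.csv(tfile)$time_s
  else
    seq_len(length(pages)) - 1
  list(frames = frames, time_s = time_s)
}

times_sidecar <- function(path) {
  paste0(sub("\\.tiff?$", "", path), "_times.csv")
}

#' Write a cohort to disk
#'
#' Writes one CSV per trace (`<trace_id>.csv` with `time_s,intensity_gs`)
#' plus a `manifest.csv` carrying per-trace metadata and ground truth.
#'
#' @param cohort A list with `traces` and `manifest`, as returned by
#'   [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in cohort$traces)
    write_trace_csv(tr, file.path(dir, paste0(tr$trace_id, ".csv")))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  traces <- lapply(seq_len(nrow(manifest)), function(i) {
    read_trace_csv(file.path(dir, paste0(manifest$trace_id[i], ".csv")),
                   trace_id = manifest$trace_id[i],
                   patient_id = manifest$patient_id[i],
                   class_label = manifest$class[i])
  })
  list(traces = traces, manifest = manifest)
}
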