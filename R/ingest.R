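#' Read a tri-axial accelerometer recording from CSV
#'
#' Expects the header `timestamp,x,y,z` with timestamps in seconds and
#' accelerations in g. Validates that every row parses to finite numbers,
#' that timestamps are strictly increasing, and (optionally) that the rate
#' inferred from the median timestamp spacing matches an expected rate.
#'
#' @param path Path to the CSV file.
#' @param participant_id Participant identifier to attach; inferred from a
#'   `recording_<id>.csv` filename if omitted.
#' @param expected_rate Expected sampling rate in Hz, or `NULL` to skip the
#'   check.
#' @param rate_tol Relative tolerance on the inferred rate (default 1%).
#' @return A `triaxial_recording` data frame (`timestamp,x,y,z`) with
#'   attributes `participant_id` and `sampling_rate` (inferred).
#' @export
read_recording <- function(path, participant_id = NULL,
                           expected_rate = NULL, rate_tol = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (!identical(trimws(header), "timestamp,x,y,z")) {
    stop("parse error in ", path, ": expected header 'timestamp,x,y,z', got '",
         header, "'", call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    stop("empty-recording error: ", path, " contains a header only",
         call. = FALSE)
  }
  num <- suppressWarnings(
    data.frame(timestamp = as.numeric(raw$timestamp),
               x = as.numeric(raw$x), y = as.numeric(raw$y),
               z = as.numeric(raw$z))
  )
  bad <- which(!stats::complete.cases(num) |
                 !is.finite(rowSums(as.matrix(num))))
  if (length(bad) > 0) {
    stop("parse error in ", path, ": malformed row at line ", bad[1] + 1,
         call. = FALSE)
  }
  d <- diff(num$timestamp)
  if (nrow(num) > 1 && any(d <= 0)) {
    stop("data error in ", path, ": timestamps not strictly increasing at line ",
         which(d <= 0)[1] + 2, call. = FALSE)
  }
  rate <- if (nrow(num) > 1) 1 / stats::median(d) else NA_real_
  if (!is.null(expected_rate) && is.finite(rate)) {
    if (abs(rate - expected_rate) / expected_rate > rate_tol) {
      stop("rate-mismatch error in ", path, ": inferred ",
           signif(rate, 6), " Hz, expected ", expected_rate, " Hz",
           call. = FALSE)
    }
    rate <- expected_rate
  } else if (is.finite(rate) && rate > 0.5 &&
             abs(rate - round(rate)) / rate < 1e-3) {
    # timestamps printed with finite precision: snap to the integer rate
    rate <- round(rate)
  }
  if (is.null(participant_id)) {
    m <- regmatches(basename(path),
                    regexec("^recording_(.+)\\.csv$", basename(path)))[[1]]
    participant_id <- if (length(m) == 2) m[2] else basename(path)
  }
  attr(num, "participant_id") <- participant_id
  attr(num, "sampling_rate") <- rate
  class(num) <- c("triaxial_recording", "data.frame")
  num
}

#' Read annotation logs from CSV
#'
#' Expects the header `participant_id,activity,start,end`. Activity names
#' must come from [activity_catalog()]; intervals within a participant must
#' not overlap. Entries are returned sorted by start time.
#'
#' @param path Path to the CSV file (may hold one or several participants).
#' @return Named list of `annotation_log` data frames, one per participant.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (!identical(trimws(header), "participant_id,activity,start,end")) {
    stop("parse error in ", path,
         ": expected header 'participant_id,activity,start,end'",
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty annotation file: ", path, call. = FALSE)
  known <- .activity_names()
  bad <- setdiff(unique(df$activity), known)
  if (length(bad) > 0) {
    stop("label error in ", path, ": unknown activity name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$start) || !is.numeric(df$end) ||
      any(!is.finite(df$start)) || any(!is.finite(df$end))) {
    stop("parse error in ", path, ": non-numeric start/end", call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    stop("annotation error in ", path, ": entry with end <= start",
         call. = FALSE)
  }
  out <- lapply(split(df, df$participant_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    rownames(g) <- NULL
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
      stop("annotation error in ", path, ": overlapping intervals for participant ",
           g$participant_id[1], call. = FALSE)
    }
    class(g) <- c("annotation_log", "data.frame")
    g
  })
  out
}

#' Trim transition noise and label recording segments
#'
#' Cuts each annotated activity interval out of the recording after
#' removing the first `trim_front` and last `trim_back` seconds (transition
#' noise at the start and end of every bout). A sample at time `t` belongs
#' to the segment when `start + trim_front <= t < end - trim_back`
#' (half-open, so no sample can belong to two segments). Samples between
#' activities are discarded. A full-length 180 s bout at 30 Hz therefore
#' retains 155 s = 4650 samples.
#'
#' @param recording A `triaxial_recording` (see [read_recording()]).
#' @param log An `annotation_log` for the same participant.
#' @param trim_front Seconds removed from the start of each bout
#'   (default 20).
#' @param trim_back Seconds removed from the end of each bout (default 5).
#' @return List of `labeled_segment` objects: each a list with
#'   `participant_id`, `activity`, `category`, `sampling_rate` and
#'   `samples` (data frame `timestamp,x,y,z`).
#' @export
align_and_trim <- function(recording, log, trim_front = 20, trim_back = 5) {
  t <- recording$timestamp
  fs <- attr(recording, "sampling_rate")
  pid <- attr(recording, "participant_id")
  if (is.null(pid)) pid <- log$participant_id[1]
  eps <- 1e-9
  segs <- vector("list", nrow(log))
  for (i in seq_len(nrow(log))) {
    start <- log$start[i]; end <- log$end[i]
    if (end - start <= trim_front + trim_back) {
      stop("degenerate-interval error: interval for '", log$activity[i],
           "' lasts ", end - start, " s, not longer than trim total ",
           trim_front + trim_back, " s", call. = FALSE)
    }
    if (t[1] > start + eps || t[length(t)] < end - 1 / fs - eps) {
      stop("coverage error: recording does not cover [", start, ", ", end,
           ") for '", log$activity[i], "'", call. = FALSE)
    }
    keep <- t >= start + trim_front - eps & t < end - trim_back - eps
    seg <- list(
      participant_id = pid,
      activity = log$activity[i],
      category = activity_category(log$activity[i]),
      sampling_rate = fs,
      samples = recording[keep, c("timestamp", "x", "y", "z"), drop = FALSE]
    )
    rownames(seg$samples) <- NULL
    class(seg) <- "labeled_segment"
    segs[[i]] <- seg
  }
  segs
}
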