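#' Names of the 49 window features, in canonical column order
#'
#' Eleven summary statistics for each of the four signals (vector magnitude
#' `vm`, then axes `x`, `y`, `z`), the two gravity-angle features, and the
#' three spectral features of the vector-magnitude series.
#'
#' @return Character vector of length 49.
#' @export
feature_names <- function() {
  per_signal <- function(s) {
    if (s == "vm") {
      c("mvm", "sdvm", "cv_vm", "min_vm", "max_vm", "lower_vm_25",
        "upper_vm_75", "third_vm", "fourth_vm", "skewness_vm", "kurtosis_vm")
    } else {
      c(paste0(c("mean_", "sd_", "cv_", "min_", "max_"), s),
        paste0("lower_", s, "_25"), paste0("upper_", s, "_75"),
        paste0(c("third_", "fourth_", "skewness_", "kurtosis_"), s))
    }
  }
  c(unlist(lapply(c("vm", "x", "y", "z"), per_signal)),
    "mangle", "sdangle", "p625", "df", "fpdf")
}

#' Per-sample vector magnitude
#'
#' Euclidean norm of the three acceleration axes, in g.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @return Numeric vector `sqrt(x^2 + y^2 + z^2)`.
#' @export
vector_magnitude <- function(x, y, z) sqrt(x^2 + y^2 + z^2)

# Eleven summary statistics of one signal. SD uses the sample (n-1)
# denominator; central moments, skewness and kurtosis use population (n)
# moments, the dominant actigraphy convention. Kurtosis is plain m4/m2^2
# (not excess). Guards: |mean| < 1e-6 g -> cv = 0; m2 < 1e-12 ->
# skewness = kurtosis = 0.
.signal_stats <- function(v) {
  n <- length(v)
  m <- mean(v)
  s <- stats::sd(v)
  cv <- if (abs(m) < 1e-6) 0 else 100 * s / abs(m)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  d <- v - m
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  if (m2 < 1e-12) {
    sk <- 0; ku <- 0
  } else {
    sk <- m3 / m2^1.5; ku <- m4 / m2^2
  }
  c(m, s, cv, min(v), max(v), q[1], q[2], m3, m4, sk, ku)
}

#' Time-domain features of a window
#'
#' The 44 per-signal summary statistics (11 each for vector magnitude and
#' the x, y, z axes) plus the two gravity-angle features. The angle series
#' is `theta_i = (180/pi) * asin(x_i / vm_i)` degrees — the tilt of the
#' device x-axis (worn along the forearm) relative to vertical — with the
#' ratio clamped to `[-1, 1]`; `mangle` and `sdangle` are its mean and
#' sample SD.
#'
#' @param x,y,z Numeric vectors (one window) of equal length `n >= 2`.
#' @return Named numeric vector of 46 features.
#' @export
time_features <- function(x, y, z) {
  n <- length(x)
  if (n < 2) stop("window-too-short error: need at least 2 samples",
                  call. = FALSE)
  vm <- vector_magnitude(x, y, z)
  ratio <- ifelse(vm < 1e-12, 0, x / vm)
  theta <- (180 / pi) * asin(pmin(1, pmax(-1, ratio)))
  out <- c(.signal_stats(vm), .signal_stats(x), .signal_stats(y),
           .signal_stats(z), mean(theta), stats::sd(theta))
  names(out) <- feature_names()[1:46]
  out
}

#' Spectral features of the vector-magnitude series
#'
#' Discrete Fourier transform moduli at positive frequencies only (the DC
#' term is excluded: the 0.6--2.5 Hz band cannot include 0 Hz, and the DC
#' modulus would otherwise dominate every spectrum). `p625` is the fraction
#' of total positive-frequency modulus within 0.6--2.5 Hz; `df` is the
#' positive frequency with the largest modulus (ties broken toward the
#' lowest frequency); `fpdf` is that largest modulus over the total. If all
#' positive-frequency moduli are below `1e-12` (constant signal) the three
#' features are 0.
#'
#' @param vm Numeric vector, the vector-magnitude series of one window
#'   (length >= 2).
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector `c(p625, df, fpdf)`.
#' @export
freq_features <- function(vm, rate) {
  n <- length(vm)
  if (n < 2) stop("window-too-short error: need at least 2 samples",
                  call. = FALSE)
  mod <- Mod(stats::fft(vm))
  k <- seq_len(n %/% 2)            # positive frequencies, Nyquist included
  f <- k * rate / n
  mo <- mod[k + 1]
  if (all(mo < 1e-12)) {
    out <- c(0, 0, 0)
  } else {
    tot <- sum(mo)
    band <- sum(mo[f >= 0.6 & f <= 2.5])
    i <- which.max(mo)             # first max = lowest frequency on ties
    out <- c(band / tot, f[i], mo[i] / tot)
  }
  names(out) <- c("p625", "df", "fpdf")
  out
}

#' All 49 features of one window
#'
#' @param x,y,z Numeric vectors (one window) of equal length.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of 49 features in [feature_names()] order.
#' @export
window_features <- function(x, y, z, rate) {
  c(time_features(x, y, z),
    freq_features(vector_magnitude(x, y, z), rate))
}

#' Segment a labeled segment into non-overlapping windows
#'
#' Consecutive windows of exactly `window_length * rate` samples are taken
#' from the start of the segment; the trailing partial window is discarded.
#' A segment shorter than one window yields zero windows (not an error).
#'
#' @param segment A `labeled_segment` from [align_and_trim()].
#' @param window_length Window length in seconds (integer in 2..16 for the
#'   study protocol; any positive length with an integral sample count is
#'   accepted).
#' @return List of `labeled_window` objects: each a list with
#'   `participant_id`, `activity`, `category`, `window_length`,
#'   `window_start_s`, `sampling_rate` and `samples`.
#' @export
segment_windows <- function(segment, window_length) {
  fs <- segment$sampling_rate
  w <- window_length * fs
  if (abs(w - round(w)) > 1e-9 || w < 1) {
    stop("window_length x sampling_rate must be a positive integer",
         call. = FALSE)
  }
  w <- round(w)
  n <- nrow(segment$samples)
  k <- n %/% w
  if (k == 0) return(list())
  lapply(seq_len(k), function(j) {
    idx <- ((j - 1) * w + 1):(j * w)
    win <- list(
      participant_id = segment$participant_id,
      activity = segment$activity,
      category = segment$category,
      window_length = window_length,
      window_start_s = segment$samples$timestamp[idx[1]],
      sampling_rate = fs,
      samples = segment$samples[idx, , drop = FALSE]
    )
    class(win) <- "labeled_window"
    win
  })
}

#' Extract the feature matrix from labeled segments
#'
#' Windows every segment with [segment_windows()] and computes the 49
#' features of every window. Column order is fixed: metadata
#' (`participant_id`, `activity`, `category`, `window_start_s`) followed by
#' the 49 features in [feature_names()] order.
#'
#' @param segments List of `labeled_segment` objects (possibly from several
#'   participants).
#' @param window_length Window length in seconds.
#' @return A data frame with one row per window.
#' @export
extract_features <- function(segments, window_length) {
  wins <- unlist(lapply(segments, segment_windows,
                        window_length = window_length),
                 recursive = FALSE)
  if (length(wins) == 0) {
    stop("empty-matrix error: no segment yields a full window of ",
         window_length, " s", call. = FALSE)
  }
  feats <- t(vapply(wins, function(w) {
    window_features(w$samples$x, w$samples$y, w$samples$z, w$sampling_rate)
  }, numeric(49)))
  meta <- data.frame(
    participant_id = vapply(wins, `[[`, "", "participant_id"),
    activity = vapply(wins, `[[`, "", "activity"),
    category = vapply(wins, `[[`, "", "category"),
    window_start_s = vapply(wins, `[[`, 0, "window_start_s"),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(feats))
}

#' Write a feature matrix to CSV
#'
#' Columns: `participant_id`, `activity`, `category`, `window_start_s`,
#' then the 49 features in [feature_names()] order.
#'
#' @param features Data frame from [extract_features()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  stopifnot(all(feature_names() %in% colnames(features)))
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
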