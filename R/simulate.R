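#' Simulation configuration for the laboratory protocol
#'
#' Builds the configuration object driving the synthetic accelerometer
#' generator. Defaults emulate the study conditions: 10 participants, each
#' performing the 10 scripted activities for 3 minutes at 30 Hz, in a
#' randomized order with a short idle break between activities.
#'
#' The generative model for every activity is
#' `acceleration = (slowly rotating unit gravity vector set by posture)
#'  + movement component + white Gaussian noise`,
#' with the movement component chosen per activity: none (lying flat),
#' low-amplitude jitter bursts (phone/computer/writing), sinusoidal arm swing
#' near 2 Hz (leisure walk), periodic raise--carry--lower cycles (moving
#' items), or randomly timed hand-to-face excursions with label-specific
#' rates and dwell times (the four face-touching activities).
#'
#' @param n_participants Number of simulated participants (default 10).
#' @param activity_duration Seconds per activity bout (default 180).
#' @param sampling_rate Sampling rate in Hz (default 30).
#' @param seed Integer seed; the single source of randomness for the whole
#'   dataset.
#' @param gap_duration Idle seconds inserted between consecutive activities
#'   (default 10), so annotation alignment is exercised downstream.
#' @param amp_sigma,freq_sigma Standard deviations of the log-normal
#'   per-participant multipliers on movement amplitude and frequency
#'   (default 0.15 each).
#' @param orient_jitter_deg Half-range in degrees of the per-participant
#'   random rotation of the baseline wrist orientation (default 15).
#' @param activity_params Named list of per-activity signal parameters; see
#'   [default_activity_params()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10,
                       activity_duration = 180,
                       sampling_rate = 30,
                       seed = 1,
                       gap_duration = 10,
                       amp_sigma = 0.15,
                       freq_sigma = 0.15,
                       orient_jitter_deg = 15,
                       activity_params = default_activity_params()) {
  cfg <- list(
    n_participants = n_participants,
    activity_duration = activity_duration,
    sampling_rate = sampling_rate,
    seed = as.integer(seed),
    gap_duration = gap_duration,
    amp_sigma = amp_sigma,
    freq_sigma = freq_sigma,
    orient_jitter_deg = orient_jitter_deg,
    activity_params = activity_params
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1 ||
      cfg$n_participants != round(cfg$n_participants)) {
    stop("configuration error: n_participants must be a positive integer",
         call. = FALSE)
  }
  if (!is.numeric(cfg$sampling_rate) || cfg$sampling_rate <= 0) {
    stop("configuration error: sampling_rate must be positive", call. = FALSE)
  }
  if (!is.numeric(cfg$activity_duration) || cfg$activity_duration <= 0) {
    stop("configuration error: activity_duration must be positive",
         call. = FALSE)
  }
  n <- cfg$activity_duration * cfg$sampling_rate
  if (abs(n - round(n)) > 1e-9 || n < 1) {
    stop("configuration error: activity_duration x sampling_rate must be a ",
         "positive integer sample count", call. = FALSE)
  }
  amps <- unlist(lapply(cfg$activity_params, function(p) {
    c(p$noise, p$jitter_amp, p$osc_amp, p$move_amp)
  }))
  if (any(amps < 0)) {
    stop("configuration error: all amplitudes must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Default per-activity signal parameters
#'
#' One parameter set per activity of [activity_catalog()]. Orientation is
#' parameterized by the tilt `theta0` of the device x-axis (along the
#' forearm) away from horizontal, in degrees, and a roll angle `phi`
#' distributing the remaining gravity between the y and z axes. `noise` is
#' the white-noise standard deviation in g. Movement models:
#' \describe{
#'   \item{static}{gravity plus noise only (lying flat, idle breaks).}
#'   \item{jitter}{small-amplitude (`jitter_amp` g) noise bursts at
#'     `burst_rate` per minute, lasting `burst_len` s (phone, computer,
#'     writing).}
#'   \item{walk}{sinusoidal arm swing at `osc_freq` Hz, amplitude `osc_amp`
#'     g spread over the axes.}
#'   \item{touch}{hand-to-face excursions: the x-axis tilt ramps from
#'     `theta0` up to `theta_face` over `raise_s` s, dwells `dwell_s` s,
#'     and ramps back, at `rate_per_min` events per minute; `move_amp` g of
#'     transient acceleration accompanies each raise/lower. `periodic =
#'     TRUE` (moving items) places cycles on a regular grid, otherwise
#'     event gaps are exponential.}
#' }
#'
#' @return Named list keyed by activity name.
#' @export
default_activity_params <- function() {
  touch <- function(rate, raise, dwell, theta_face, noise, move_amp = 0.12,
                    periodic = FALSE) {
    list(model = "touch", theta0 = 15, phi = 45, noise = noise,
         rate_per_min = rate, raise_s = raise, dwell_s = dwell,
         theta_face = theta_face, move_amp = move_amp, periodic = periodic)
  }
  jit <- function(theta0, phi, amp, burst_rate, burst_len) {
    list(model = "jitter", theta0 = theta0, phi = phi, noise = 0.015,
         jitter_amp = amp, burst_rate = burst_rate, burst_len = burst_len)
  }
  list(
    "Using mobile phone"     = jit(25, 40, 0.04, 20, 0.6),
    "Lying flat on the back" = list(model = "static", theta0 = 0, phi = 80,
                                    noise = 0.01),
    "Computer tasks"         = jit(30, 50, 0.05, 25, 0.5),
    "Writing"                = jit(35, 45, 0.04, 15, 0.8),
    "Leisure walk"           = list(model = "walk", theta0 = 80, phi = 30,
                                    noise = 0.03, osc_freq = 2.0,
                                    osc_amp = 0.3),
    "Moving items from one location to another" =
      touch(rate = 12, raise = 0.8, dwell = 2.5, theta_face = 65,
            noise = 0.03, move_amp = 0.15, periodic = TRUE),
    "Repeated face touching" =
      touch(rate = 10, raise = 0.7, dwell = 1.5, theta_face = 70,
            noise = 0.02),
    "Eating and drinking"    =
      touch(rate = 5, raise = 0.8, dwell = 3.0, theta_face = 68,
            noise = 0.02),
    "Simulated smoking"      =
      touch(rate = 4, raise = 0.8, dwell = 6.0, theta_face = 70,
            noise = 0.015),
    "Adjusting eyeglass"     =
      touch(rate = 8, raise = 0.7, dwell = 1.0, theta_face = 72,
            noise = 0.015)
  )
}

#' Draw per-participant random effects
#'
#' Log-normal multipliers on movement amplitude and frequency and a small
#' random rotation of the baseline wrist orientation, producing realistic
#' between-subject variance so leave-one-subject-out folds are non-trivial.
#' Draws from the current RNG stream.
#'
#' @param cfg A [sim_config()].
#' @return List with `amp_mult`, `freq_mult`, `dtheta`, `dphi`.
#' @export
participant_effects <- function(cfg) {
  j <- cfg$orient_jitter_deg
  list(
    amp_mult  = exp(stats::rnorm(1, 0, cfg$amp_sigma)),
    freq_mult = exp(stats::rnorm(1, 0, cfg$freq_sigma)),
    dtheta    = stats::runif(1, -j, j),
    dphi      = stats::runif(1, -j, j)
  )
}

.neutral_effects <- function() {
  list(amp_mult = 1, freq_mult = 1, dtheta = 0, dphi = 0)
}

# Event onset times within [0, duration - cycle]. Periodic events sit on a
# regular grid with a random phase; aperiodic events use exponential gaps
# whose mean keeps the long-run rate near rate_per_min.
.event_starts <- function(duration, rate_per_min, cycle_len, periodic) {
  if (periodic) {
    period <- 60 / rate_per_min
    ph <- stats::runif(1, 0, max(period - cycle_len, 0.01))
    starts <- seq(ph, duration - cycle_len, by = period)
  } else {
    mean_gap <- max(60 / rate_per_min - cycle_len, 0.5)
    starts <- numeric(0)
    t <- stats::rexp(1, 1 / mean_gap)
    while (t + cycle_len < duration) {
      starts <- c(starts, t)
      t <- t + cycle_len + stats::rexp(1, 1 / mean_gap)
    }
  }
  starts
}

# Excursion shape (0 at rest, 1 at the face) and transition indicator
# (sin half-wave during raise/lower) for a set of events.
.touch_profile <- function(tt, starts, raise, dwell) {
  shape <- numeric(length(tt))
  trans <- numeric(length(tt))
  for (s in starts) {
    up <- which(tt >= s & tt < s + raise)
    u <- (tt[up] - s) / raise
    shape[up] <- (1 - cos(pi * u)) / 2
    trans[up] <- sin(pi * u)
    hold <- which(tt >= s + raise & tt < s + raise + dwell)
    shape[hold] <- 1
    down <- which(tt >= s + raise + dwell & tt < s + 2 * raise + dwell)
    u <- (tt[down] - (s + raise + dwell)) / raise
    shape[down] <- (1 + cos(pi * u)) / 2
    trans[down] <- -sin(pi * u)
  }
  list(shape = shape, trans = trans)
}

#' Simulate one activity bout for one participant
#'
#' Generates `activity_duration * sampling_rate` samples of tri-axial
#' acceleration (in g) for a single scripted activity, using the generative
#' model described in [sim_config()]. Draws from the current RNG stream:
#' call `set.seed()` (or let [simulate_dataset()] thread the seed) for
#' reproducibility.
#'
#' @param activity Activity name from [activity_catalog()].
#' @param cfg A [sim_config()].
#' @param effects Per-participant random effects from
#'   [participant_effects()]; neutral effects if omitted.
#' @return Data frame with columns `t` (seconds from bout start), `x`, `y`,
#'   `z` (g).
#' @export
simulate_activity <- function(activity, cfg, effects = NULL) {
  validate_sim_config(cfg)
  p <- cfg$activity_params[[activity]]
  if (is.null(p)) {
    stop("configuration error: no signal parameters for activity '",
         activity, "'", call. = FALSE)
  }
  if (is.null(effects)) effects <- .neutral_effects()
  .simulate_segment(p, cfg$activity_duration, cfg$sampling_rate, effects)
}

.simulate_segment <- function(p, duration, fs, effects) {
  n <- round(duration * fs)
  if (n < 1) stop("configuration error: non-positive sample count",
                  call. = FALSE)
  tt <- (seq_len(n) - 1) / fs
  deg <- pi / 180

  theta0 <- p$theta0 + effects$dtheta
  phi <- (p$phi + effects$dphi) * deg
  # slow postural wobble so orientation is never perfectly static
  theta <- theta0 + 2 * sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi))

  mx <- numeric(n); my <- numeric(n); mz <- numeric(n)
  amp <- effects$amp_mult

  if (p$model == "walk") {
    f <- p$osc_freq * effects$freq_mult
    a <- p$osc_amp * amp
    ph <- stats::runif(3, 0, 2 * pi)
    # arm hangs nearly vertical while walking, so the dominant swing lies
    # along the forearm (x) axis and modulates the magnitude at the swing
    # frequency rather than its second harmonic
    mx <- a * sin(2 * pi * f * tt + ph[1])
    my <- 0.4 * a * sin(2 * pi * f * tt + ph[1] + 1.2)
    mz <- 0.25 * a * sin(2 * pi * f * tt + ph[2])
  } else if (p$model == "jitter") {
    starts <- .event_starts(duration, p$burst_rate, p$burst_len,
                            periodic = FALSE)
    env <- numeric(n)
    for (s in starts) {
      idx <- which(tt >= s & tt < s + p$burst_len)
      env[idx] <- sin(pi * (tt[idx] - s) / p$burst_len)
    }
    a <- p$jitter_amp * amp
    mx <- a * env * stats::rnorm(n)
    my <- a * env * stats::rnorm(n)
    mz <- a * env * stats::rnorm(n)
  } else if (p$model == "touch") {
    cycle <- 2 * p$raise_s + p$dwell_s
    starts <- .event_starts(duration, p$rate_per_min * effects$freq_mult,
                            cycle, periodic = isTRUE(p$periodic))
    prof <- .touch_profile(tt, starts, p$raise_s, p$dwell_s)
    theta <- theta + (p$theta_face - p$theta0) * prof$shape
    a <- p$move_amp * amp
    mx <- a * prof$trans
    my <- -0.6 * a * prof$trans
    mz <- 0.3 * a * prof$trans
  }

  gx <- sin(theta * deg)
  gy <- cos(theta * deg) * cos(phi)
  gz <- cos(theta * deg) * sin(phi)

  data.frame(
    t = tt,
    x = gx + mx + stats::rnorm(n, 0, p$noise),
    y = gy + my + stats::rnorm(n, 0, p$noise),
    z = gz + mz + stats::rnorm(n, 0, p$noise)
  )
}

# idle-break signal between activities: resting posture plus noise
.simulate_idle <- function(duration, fs) {
  p <- list(model = "static", theta0 = 20, phi = 45, noise = 0.02)
  .simulate_segment(p, duration, fs, .neutral_effects())
}

#' Simulate the full multi-participant dataset
#'
#' One continuous recording and one annotation log per participant. Each
#' participant performs all ten activities exactly once, in an order
#' shuffled per participant, with an idle gap between bouts. Per-participant
#' random effects are drawn once. All randomness flows through a single RNG
#' stream seeded from `cfg$seed`, so output is bit-identical across calls
#' with the same configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `recordings` (list of `triaxial_recording` data frames
#'   with columns `timestamp,x,y,z` and attributes `participant_id`,
#'   `sampling_rate`) and `logs` (list of `annotation_log` data frames with
#'   columns `participant_id,activity,start,end`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  acts <- .activity_names()
  fs <- cfg$sampling_rate
  dur <- cfg$activity_duration
  gap <- cfg$gap_duration

  recordings <- vector("list", cfg$n_participants)
  logs <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", i)
    effects <- participant_effects(cfg)
    order_i <- sample(length(acts))

    blocks <- list()
    entries <- list()
    offset <- 0
    for (k in seq_along(order_i)) {
      act <- acts[order_i[k]]
      seg <- simulate_activity(act, cfg, effects)
      blocks[[length(blocks) + 1]] <- seg[, c("x", "y", "z")]
      entries[[k]] <- data.frame(
        participant_id = pid, activity = act,
        start = offset, end = offset + dur,
        stringsAsFactors = FALSE
      )
      offset <- offset + dur
      if (k < length(order_i) && gap > 0) {
        blocks[[length(blocks) + 1]] <-
          .simulate_idle(gap, fs)[, c("x", "y", "z")]
        offset <- offset + gap
      }
    }
    xyz <- do.call(rbind, blocks)
    rec <- data.frame(
      timestamp = (seq_len(nrow(xyz)) - 1) / fs,
      x = xyz$x, y = xyz$y, z = xyz$z
    )
    attr(rec, "participant_id") <- pid
    attr(rec, "sampling_rate") <- fs
    class(rec) <- c("triaxial_recording", "data.frame")
    recordings[[i]] <- rec

    log <- do.call(rbind, entries)
    class(log) <- c("annotation_log", "data.frame")
    logs[[i]] <- log
  }
  names(recordings) <- vapply(recordings, attr, "", "participant_id")
  names(logs) <- names(recordings)
  list(recordings = recordings, logs = logs)
}

#' Write a simulated dataset to CSV files
#'
#' Writes one recording CSV (`recording_<id>.csv`, header
#' `timestamp,x,y,z`, timestamps with 6 decimals) and one annotation CSV
#' (`annotations_<id>.csv`, header `participant_id,activity,start,end`) per
#' participant, plus `manifest.json` recording the generating seed and
#' configuration scalars. Output is byte-identical across runs with the
#' same configuration.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param cfg The [sim_config()] used, stored in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(sim, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("output directory not writable: ", dir,
                             call. = FALSE)
  for (rec in sim$recordings) {
    pid <- attr(rec, "participant_id")
    path <- file.path(dir, paste0("recording_", pid, ".csv"))
    lines <- c("timestamp,x,y,z",
               sprintf("%.6f,%.6f,%.6f,%.6f",
                       rec$timestamp, rec$x, rec$y, rec$z))
    writeLines(lines, path)
  }
  for (log in sim$logs) {
    pid <- log$participant_id[1]
    path <- file.path(dir, paste0("annotations_", pid, ".csv"))
    lines <- c("participant_id,activity,start,end",
               sprintf("%s,%s,%.6f,%.6f",
                       log$participant_id, log$activity, log$start, log$end))
    writeLines(lines, path)
  }
  manifest <- list(
    n_participants = length(sim$recordings),
    participant_ids = names(sim$recordings)
  )
  if (!is.null(cfg)) {
    manifest$seed <- cfg$seed
    manifest$sampling_rate <- cfg$sampling_rate
    manifest$activity_duration <- cfg$activity_duration
    manifest$gap_duration <- cfg$gap_duration
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
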