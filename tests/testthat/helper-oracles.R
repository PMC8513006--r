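# Independent brute-force oracles used to check the feature and metric
# implementations. Deliberately naive: explicit loops, direct-summation DFT
# (not FFT), textbook quantile interpolation.

naive_signal_stats <- function(v) {
  n <- length(v)
  m <- 0
  for (i in seq_len(n)) m <- m + v[i]
  m <- m / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (v[i] - m)^2
  s <- sqrt(ss / (n - 1))
  cv <- if (abs(m) < 1e-6) 0 else 100 * s / abs(m)
  sv <- sort(v)
  qlin <- function(p) {            # type-7: linear between order statistics
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    sv[lo] + (h - lo) * (sv[hi] - sv[lo])
  }
  m2 <- 0; m3 <- 0; m4 <- 0
  for (i in seq_len(n)) {
    d <- v[i] - m
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  if (m2 < 1e-12) {
    sk <- 0; ku <- 0
  } else {
    sk <- m3 / m2^1.5; ku <- m4 / m2^2
  }
  c(m, s, cv, min(v), max(v), qlin(0.25), qlin(0.75), m3, m4, sk, ku)
}

# direct-summation DFT of the positive-frequency moduli
naive_freq_features <- function(vm, rate) {
  n <- length(vm)
  nf <- n %/% 2
  j <- 0:(n - 1)
  mo <- numeric(nf)
  fr <- numeric(nf)
  for (k in seq_len(nf)) {
    ang <- -2 * pi * k * j / n
    mo[k] <- sqrt(sum(vm * cos(ang))^2 + sum(vm * sin(ang))^2)
    fr[k] <- k * rate / n
  }
  if (max(mo) < 1e-12) return(c(0, 0, 0))
  tot <- sum(mo)
  band <- sum(mo[fr >= 0.6 & fr <= 2.5])
  i <- which.max(mo)
  c(band / tot, fr[i], mo[i] / tot)
}

naive_window_features <- function(x, y, z, rate) {
  n <- length(x)
  vm <- numeric(n)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    vm[i] <- sqrt(x[i]^2 + y[i]^2 + z[i]^2)
    r <- if (vm[i] < 1e-12) 0 else x[i] / vm[i]
    theta[i] <- asin(max(-1, min(1, r))) * 180 / pi
  }
  out <- c(naive_signal_stats(vm), naive_signal_stats(x),
           naive_signal_stats(y), naive_signal_stats(z),
           mean(theta), stats::sd(theta),
           naive_freq_features(vm, rate))
  names(out) <- feature_names()
  out
}

# random window of plausible accelerometer-like data
random_window <- function(n = 150, rate = 30) {
  base <- stats::runif(3, -1, 1)
  f <- stats::runif(1, 0.3, 5)
  t <- (seq_len(n) - 1) / rate
  a <- stats::runif(1, 0, 0.5)
  list(
    x = base[1] + a * sin(2 * pi * f * t) + stats::rnorm(n, 0, 0.05),
    y = base[2] + a * cos(2 * pi * f * t) + stats::rnorm(n, 0, 0.05),
    z = base[3] + stats::rnorm(n, 0, 0.05),
    rate = rate
  )
}

# wrap raw sample arrays as a labeled_segment
make_segment <- function(x, y, z, rate = 30, activity = "Writing",
                         participant_id = "P01", t0 = 0) {
  seg <- list(
    participant_id = participant_id,
    activity = activity,
    category = activity_category(activity),
    sampling_rate = rate,
    samples = data.frame(
      timestamp = t0 + (seq_along(x) - 1) / rate,
      x = x, y = y, z = z
    )
  )
  class(seg) <- "labeled_segment"
  seg
}

# small simulated dataset shared by several test files
small_sim <- function(n_participants = 2, duration = 60, seed = 42) {
  sim_config(n_participants = n_participants, activity_duration = duration,
             seed = seed, gap_duration = 5)
}

segments_of <- function(sim, trim_front = 20, trim_back = 5) {
  unlist(lapply(names(sim$recordings), function(pid) {
    align_and_trim(sim$recordings[[pid]], sim$logs[[pid]],
                   trim_front, trim_back)
  }), recursive = FALSE)
}
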