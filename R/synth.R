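#' Per-activity generative parameters
#'
#' Each activity is generated as gravity projected onto a body-fixed
#' orientation, plus a per-axis sinusoidal gait oscillation whose phase is
#' redrawn every stride cycle (so the signal is only quasi-periodic), plus
#' white noise; the barometer channel is a baseline plus a signed
#' altitude-drift ramp plus white noise.
#'
#' @param orientation unit 3-vector: direction of gravity in device
#'   coordinates.
#' @param amp per-axis oscillation amplitude, m/s^2 (length 3).
#' @param freq_hz stride frequency, Hz.
#' @param noise_sd accelerometer white-noise SD, m/s^2.
#' @param drift_hpa_s pressure drift rate, hPa/s — negative while climbing
#'   upstairs (pressure falls with altitude), positive going downstairs,
#'   zero on flat ground.
#' @param p_noise_sd barometer white-noise SD, hPa (default 0.012, typical
#'   RMS noise of a phone barometer).
#' @return An `activity_params` list.
#' @export
activity_params <- function(orientation, amp, freq_hz, noise_sd,
                            drift_hpa_s = 0, p_noise_sd = 0.012) {
  har_assert(length(orientation) == 3 && abs(sqrt(sum(orientation^2)) - 1) < 1e-6,
             "`orientation` must be a unit 3-vector")
  har_assert(length(amp) == 3 && all(amp >= 0), "`amp` must be 3 non-negative values")
  har_assert(freq_hz > 0 && noise_sd >= 0 && p_noise_sd >= 0,
             "frequency must be positive, noise SDs non-negative")
  list(orientation = orientation, amp = amp, freq_hz = freq_hz,
       noise_sd = noise_sd, drift_hpa_s = drift_hpa_s, p_noise_sd = p_noise_sd)
}

#' Default six-activity parameter set
#'
#' Upright activities put gravity almost entirely on +Y (phone vertical in
#' a trouser pocket); sitting rotates the device by ~60 degrees so the
#' Y-axis mean drops.  Stride frequencies: walking 1.8 Hz, running
#' 2.8 Hz, stairs 1.5 Hz — human gait is around 2 Hz.  Oscillation
#' amplitudes enforce the motion-intensity ordering
#' standing < walking < running.  Stair pressure drifts are about
#' 0.04 hPa/s (roughly 0.3-0.4 m/s of vertical speed at ~0.12 hPa/m),
#' with descent faster than ascent.
#'
#' @return Named list of [activity_params()], one per activity.
#' @export
default_activity_params <- function() {
  upright <- c(0, 1, 0)
  seated <- c(sin(pi / 3), cos(pi / 3), 0)   # device tipped ~60 degrees
  list(
    sitting    = activity_params(seated,  c(0.02, 0.03, 0.02), 0.3, 0.05),
    standing   = activity_params(upright, c(0.03, 0.05, 0.03), 0.4, 0.05),
    walking    = activity_params(upright, c(0.8, 2.0, 1.2),    1.8, 0.10),
    running    = activity_params(upright, c(6.0, 2.0, 5.0),    2.8, 0.15),
    upstairs   = activity_params(upright, c(0.9, 1.9, 1.1),    1.5, 0.10,
                                 drift_hpa_s = -0.035),
    downstairs = activity_params(upright, c(1.0, 1.8, 1.2),    1.5, 0.10,
                                 drift_hpa_s = 0.05)
  )
}

#' Synthetic session configuration
#'
#' @param activities named list of [activity_params()]; defaults to
#'   [default_activity_params()].
#' @param rate_hz sampling rate for both channels, Hz (default 50, a
#'   typical phone IMU rate; decimate or set 1 for the low-rate regime).
#' @param schedule data.frame with columns `activity`, `duration_s`
#'   describing the session, in order.
#' @param seed integer seed; the whole session is reproducible from it.
#' @param baseline_hpa starting pressure (default 1013.25).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(activities = default_activity_params(),
                             rate_hz = 50,
                             schedule = data.frame(
                               activity = names(default_activity_params()),
                               duration_s = 60),
                             seed = 1L, baseline_hpa = 1013.25) {
  har_assert(rate_hz > 0, "`rate_hz` must be positive")
  har_assert(all(c("activity", "duration_s") %in% names(schedule)),
             "`schedule` needs columns activity and duration_s")
  har_assert(all(schedule$duration_s > 0), "schedule durations must be positive")
  unknown <- setdiff(schedule$activity, names(activities))
  if (length(unknown) > 0) {
    har_error(sprintf("unknown activity in schedule: %s",
                      paste(unknown, collapse = ", ")), "har_param_error")
  }
  structure(list(activities = activities, rate_hz = rate_hz,
                 schedule = schedule, seed = as.integer(seed),
                 baseline_hpa = baseline_hpa),
            class = "synthetic_config")
}

# One activity segment: n samples starting at phase time 0.
segment_accel <- function(par, n, rate_hz) {
  t_rel <- (seq_len(n) - 1) / rate_hz
  cycle <- floor(t_rel * par$freq_hz)
  n_cycles <- max(cycle) + 1
  osc <- matrix(0, n, 3)
  for (ax in 1:3) {
    phase <- runif(n_cycles, 0, 2 * pi)        # fresh phase each stride cycle
    osc[, ax] <- par$amp[ax] * sin(2 * pi * par$freq_hz * t_rel + phase[cycle + 1])
  }
  grav <- matrix(9.81 * par$orientation, n, 3, byrow = TRUE)
  grav + osc + matrix(rnorm(n * 3, 0, par$noise_sd), n, 3)
}

#' Generate a labelled synthetic session
#'
#' Walks the schedule, generating accelerometer and barometer samples at
#' the configured rate with per-sample ground-truth labels.  Pressure
#' drift accumulates across segments (altitude persists when the activity
#' changes).  Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A labelled [sensor_stream()].
#' @export
generate_session <- function(config) {
  har_assert(inherits(config, "synthetic_config"),
             "`config` must be a synthetic_config")
  set.seed(config$seed)
  rate <- config$rate_hz
  acc <- list(); labs <- list(); drift <- list()
  for (i in seq_len(nrow(config$schedule))) {
    a <- config$schedule$activity[i]
    par <- config$activities[[a]]
    n <- round(config$schedule$duration_s[i] * rate)
    acc[[i]] <- segment_accel(par, n, rate)
    labs[[i]] <- rep(a, n)
    drift[[i]] <- rep(par$drift_hpa_s / rate, n)
  }
  acc <- do.call(rbind, acc)
  labs <- unlist(labs)
  n_tot <- nrow(acc)
  t <- (seq_len(n_tot) - 1) / rate
  p_noise <- vapply(labs, function(a) config$activities[[a]]$p_noise_sd, numeric(1))
  p <- config$baseline_hpa + cumsum(unlist(drift)) - unlist(drift)[1] +
    rnorm(n_tot, 0, 1) * p_noise
  sensor_stream(
    data.frame(t = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3]),
    data.frame(t = t, p = p),
    labels = labs, rate_hz = rate)
}

#' Generate a balanced, trimmed training set
#'
#' Emulates the training protocol: each activity is recorded as its own
#' session, cut into non-overlapping windows, and the first and last
#' window of every session are discarded ([trim_session()]) so only
#' steady-state windows remain — exactly `windows_per_class` windows per
#' activity.  With 15 windows per class over six activities this yields
#' the canonical 90-window training set.
#'
#' @param config a [synthetic_config()]; its schedule is ignored — one
#'   session per activity is generated, with a per-activity sub-seed
#'   derived from `config$seed`.
#' @param windows_per_class windows to keep per activity (default 15).
#' @param window_s window length in seconds (default 5).
#' @return List of labelled windows
#'   (`length = windows_per_class * n_activities`).
#' @export
generate_training_set <- function(config, windows_per_class = 15, window_s = 5) {
  har_assert(inherits(config, "synthetic_config"),
             "`config` must be a synthetic_config")
  har_assert(windows_per_class >= 1, "`windows_per_class` must be >= 1")
  acts <- names(config$activities)
  out <- list()
  for (i in seq_along(acts)) {
    cfg_i <- config
    # +2 windows so trimming the first and last leaves windows_per_class.
    cfg_i$schedule <- data.frame(activity = acts[i],
                                 duration_s = (windows_per_class + 2) * window_s)
    cfg_i$seed <- as.integer((config$seed + 131L * i) %% .Machine$integer.max)
    w <- trim_session(window_stream(generate_session(cfg_i), window_s))
    out <- c(out, w)
  }
  out
}
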