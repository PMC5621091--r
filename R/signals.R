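#' Construct a sensor stream
#'
#' A sensor stream bundles time-stamped tri-axial accelerometer samples
#' (m/s^2, gravity included), optional barometric pressure samples (hPa),
#' optional per-accelerometer-sample activity labels, and the nominal
#' sampling rate.  Both channels must be sorted by time.
#'
#' @param accel data.frame with columns `t` (seconds), `ax`, `ay`, `az`
#'   (m/s^2).
#' @param pressure data.frame with columns `t` (seconds) and `p` (hPa), or
#'   `NULL` for accelerometer-only streams.
#' @param labels character vector of activity labels, one per accelerometer
#'   sample, or `NULL`.
#' @param rate_hz nominal sampling rate in Hz.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(accel, pressure = NULL, labels = NULL, rate_hz) {
  har_assert(is.data.frame(accel) && all(c("t", "ax", "ay", "az") %in% names(accel)),
             "`accel` must be a data.frame with columns t, ax, ay, az")
  har_assert(nrow(accel) > 0, "sensor stream has no accelerometer samples",
             "har_empty_stream")
  har_assert(all(is.finite(accel$t)) && !is.unsorted(accel$t),
             "accelerometer timestamps must be finite and non-decreasing")
  if (is.null(pressure)) {
    pressure <- data.frame(t = numeric(0), p = numeric(0))
  }
  har_assert(all(c("t", "p") %in% names(pressure)),
             "`pressure` must have columns t and p")
  har_assert(!is.unsorted(pressure$t), "pressure timestamps must be non-decreasing")
  har_assert(all(pressure$p > 0), "pressure values must be positive (hPa)")
  if (!is.null(labels)) {
    har_assert(length(labels) == nrow(accel),
               "need exactly one label per accelerometer sample")
    labels <- as.character(labels)
  }
  har_assert(is.numeric(rate_hz) && length(rate_hz) == 1 && rate_hz > 0,
             "`rate_hz` must be a single positive number")
  structure(
    list(accel = accel[, c("t", "ax", "ay", "az")],
         pressure = pressure[, c("t", "p")],
         labels = labels, rate_hz = rate_hz),
    class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d accel / %d pressure samples @ %g Hz",
              nrow(x$accel), nrow(x$pressure), x$rate_hz))
  if (!is.null(x$labels)) {
    cat(sprintf(", labels: %s", paste(unique(x$labels), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' A sampling scheme: rate and window length
#'
#' @param rate_hz sampling rate in Hz.
#' @param window_s window length in seconds.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(rate_hz, window_s) {
  har_assert(rate_hz > 0 && window_s > 0,
             "rate_hz and window_s must both be positive")
  structure(list(rate_hz = rate_hz, window_s = window_s),
            class = "sampling_scheme")
}

# Majority label of a window; ties broken by earliest occurrence.
majority_label <- function(labels) {
  if (length(labels) == 0) return(NA_character_)
  counts <- table(labels)
  modes <- names(counts)[counts == max(counts)]
  labels[match(TRUE, labels %in% modes)]
}

#' Cut a sensor stream into fixed-length windows
#'
#' Windows are half-open intervals `[start, start + window_s)` anchored at
#' the stream's first accelerometer timestamp, advancing by
#' `window_s - overlap_s`.  A trailing partial window is dropped.  Pressure
#' samples are assigned to the window containing their timestamp; the two
#' channels need not share timestamps.  When labels are present each window
#' carries the majority label of its samples (ties broken by earliest
#' label).
#'
#' @param stream a [sensor_stream()].
#' @param window_s window length in seconds.
#' @param overlap_s overlap between consecutive windows in seconds
#'   (default 0, i.e. non-overlapping tiling).
#' @return A list of `sensor_window` objects, each with fields `t_start`,
#'   `duration`, `accel`, `pressure`, `label`.
#' @export
window_stream <- function(stream, window_s, overlap_s = 0) {
  har_assert(inherits(stream, "sensor_stream"), "`stream` must be a sensor_stream")
  har_assert(nrow(stream$accel) > 0, "cannot window an empty stream",
             "har_empty_stream")
  har_assert(window_s > overlap_s && overlap_s >= 0,
             "need window_s > overlap_s >= 0")
  t <- stream$accel$t
  anchor <- t[1]
  # Span includes one sampling period so that e.g. 10 samples at 1 Hz fill
  # exactly two 5 s windows.
  span <- t[length(t)] - anchor + 1 / stream$rate_hz
  step <- window_s - overlap_s
  n_win <- floor((span - overlap_s) / step)
  if (n_win < 1) return(list())
  lapply(seq_len(n_win) - 1, function(i) {
    t0 <- anchor + i * step
    in_a <- t >= t0 & t < t0 + window_s
    in_p <- stream$pressure$t >= t0 & stream$pressure$t < t0 + window_s
    lab <- if (is.null(stream$labels)) NA_character_ else
      majority_label(stream$labels[in_a])
    structure(list(t_start = t0, duration = window_s,
                   accel = stream$accel[in_a, , drop = FALSE],
                   pressure = stream$pressure[in_p, , drop = FALSE],
                   label = lab),
              class = "sensor_window")
  })
}

#' Drop the first and last window of a session
#'
#' Recording sessions begin and end with the subject getting into and out
#' of the activity, so the opening and closing windows are discarded to
#' keep only steady-state data.
#'
#' @param windows a list of windows from [window_stream()].
#' @return The interior windows, order preserved.  With exactly two
#'   windows nothing interior remains: an empty list is returned with a
#'   warning.
#' @export
trim_session <- function(windows) {
  har_assert(length(windows) >= 2, "trim_session needs at least 2 windows")
  if (length(windows) < 3) {
    warning("fewer than 3 windows: nothing interior remains after trimming")
    return(list())
  }
  windows[seq(2, length(windows) - 1)]
}

#' Decimate a stream to a lower sampling rate
#'
#' Keeps every (rate_hz/target_hz)-th sample starting from the first, on
#' both channels, with no interpolation or anti-alias filtering.  This
#' reproduces what a sensor genuinely polled at the lower rate would have
#' recorded, which is the point of running the recogniser at a low rate:
#' point sampling, not digital downsampling.
#'
#' @param stream a [sensor_stream()].
#' @param target_hz target rate; must divide `stream$rate_hz` evenly.
#' @return A [sensor_stream()] at `target_hz`.
#' @export
decimate <- function(stream, target_hz) {
  har_assert(inherits(stream, "sensor_stream"), "`stream` must be a sensor_stream")
  stride <- stream$rate_hz / target_hz
  if (abs(stride - round(stride)) > 1e-9 || stride < 1) {
    har_error(sprintf(
      "target rate %g Hz does not divide the stream rate %g Hz into an integer stride",
      target_hz, stream$rate_hz), "har_param_error")
  }
  stride <- as.integer(round(stride))
  keep <- function(n) seq(1L, n, by = stride)
  ka <- keep(nrow(stream$accel))
  kp <- if (nrow(stream$pressure) > 0) keep(nrow(stream$pressure)) else integer(0)
  sensor_stream(stream$accel[ka, , drop = FALSE],
                stream$pressure[kp, , drop = FALSE],
                if (is.null(stream$labels)) NULL else stream$labels[ka],
                rate_hz = target_hz)
}

#' Equivalent window length at a low sampling rate
#'
#' When the sampling rate drops below the Nyquist rate of the activity
#' (twice the dominant activity frequency), the same statistical content
#' can be recovered by lengthening the window so that the sample count is
#' preserved: `T_low = (2 * activity_hz * ref_window_s) / low_rate_hz`.
#'
#' @param activity_hz dominant activity frequency Fa in Hz (about 2 Hz for
#'   human gait).
#' @param ref_window_s reference window length in seconds used at the
#'   Nyquist rate.
#' @param low_rate_hz the low sampling rate in Hz.
#' @return Window length in seconds.
#' @export
equivalent_window <- function(activity_hz, ref_window_s, low_rate_hz) {
  har_assert(activity_hz > 0 && ref_window_s > 0 && low_rate_hz > 0,
             "all arguments must be positive")
  (2 * activity_hz * ref_window_s) / low_rate_hz
}

#' Compare the pooled statistics of two sampling schemes
#'
#' Applies each scheme to the same stream (decimating to the scheme's rate,
#' then windowing by its window length, dropping trailing partial windows),
#' pools the windowed accelerometer samples, and reports per-axis mean and
#' variance under each scheme together with their absolute relative
#' differences.  The two schemes must satisfy the sample-count contract
#' `rate_hz * window_s` equal on both sides, so each window carries the
#' same number of samples.
#'
#' @param stream a [sensor_stream()]; its rate must be an integer multiple
#'   of each scheme's rate.
#' @param scheme_a,scheme_b [sampling_scheme()] objects with equal
#'   rate-by-window products.
#' @return A list with per-scheme `mean` and `var` (named ax/ay/az),
#'   `rel_diff_mean`, `rel_diff_var`, and the pooled sample matrices
#'   `values_a`, `values_b`.
#' @export
scheme_equivalence_stats <- function(stream, scheme_a, scheme_b) {
  har_assert(inherits(scheme_a, "sampling_scheme") &&
             inherits(scheme_b, "sampling_scheme"),
             "schemes must be sampling_scheme objects")
  pa <- scheme_a$rate_hz * scheme_a$window_s
  pb <- scheme_b$rate_hz * scheme_b$window_s
  if (abs(pa - pb) > 1e-9) {
    har_error(sprintf(
      "schemes are not sample-count equivalent: %g Hz x %g s = %g but %g Hz x %g s = %g (the rate-by-window products must match)",
      scheme_a$rate_hz, scheme_a$window_s, pa,
      scheme_b$rate_hz, scheme_b$window_s, pb), "har_param_error")
  }
  pool <- function(scheme) {
    s <- decimate(stream, scheme$rate_hz)
    w <- window_stream(s, scheme$window_s)
    har_assert(length(w) > 0, "stream too short for the scheme's window",
               "har_empty_stream")
    do.call(rbind, lapply(w, function(x) as.matrix(x$accel[, c("ax", "ay", "az")])))
  }
  va <- pool(scheme_a)
  vb <- pool(scheme_b)
  ma <- colMeans(va); mb <- colMeans(vb)
  # population (1/n) variance: the moments of the pooled sample multiset,
  # so multisets that are equal up to multiplicity compare exactly
  pvar <- function(m) colMeans(sweep(m, 2, colMeans(m))^2)
  sa <- pvar(va); sb <- pvar(vb)
  rel <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)
  list(mean_a = ma, mean_b = mb, var_a = sa, var_b = sb,
       rel_diff_mean = rel(ma, mb), rel_diff_var = rel(sa, sb),
       values_a = va, values_b = vb)
}

#' Read / write sensor streams as CSV
#'
#' The on-disk format is a single UTF-8 CSV with header row and columns
#' `t,ax,ay,az,p,label`; `p` and `label` may be empty.
#'
#' @param path file path.
#' @param rate_hz nominal rate; if `NULL`, inferred from the median
#'   timestamp spacing.
#' @return [read_sensor_csv()] returns a [sensor_stream()];
#'   [write_sensor_csv()] returns `path` invisibly.
#' @export
read_sensor_csv <- function(path, rate_hz = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  har_assert(all(c("t", "ax", "ay", "az") %in% names(d)),
             "CSV must have columns t, ax, ay, az (and optionally p, label)")
  har_assert(nrow(d) > 0, "sensor CSV contains no samples", "har_empty_stream")
  if (is.null(rate_hz)) {
    dt <- stats::median(diff(d$t))
    har_assert(is.finite(dt) && dt > 0, "cannot infer sampling rate from timestamps")
    rate_hz <- 1 / dt
  }
  pressure <- NULL
  if ("p" %in% names(d) && any(!is.na(d$p))) {
    pressure <- d[!is.na(d$p), c("t", "p")]
  }
  labels <- NULL
  if ("label" %in% names(d) && any(nzchar(d$label) & !is.na(d$label))) {
    labels <- d$label
  }
  sensor_stream(d[, c("t", "ax", "ay", "az")], pressure, labels, rate_hz)
}

#' @rdname read_sensor_csv
#' @param stream a [sensor_stream()] to write.
#' @export
write_sensor_csv <- function(stream, path) {
  har_assert(inherits(stream, "sensor_stream"), "`stream` must be a sensor_stream")
  d <- stream$accel
  d$p <- NA_real_
  if (nrow(stream$pressure) > 0) {
    idx <- match(round(stream$pressure$t, 9), round(d$t, 9))
    ok <- !is.na(idx)
    d$p[idx[ok]] <- stream$pressure$p[ok]
  }
  d$label <- if (is.null(stream$labels)) "" else stream$labels
  write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
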