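#' Per-window features
#'
#' Six features are computed per window, chosen for low sensor and compute
#' cost:
#' * `Pd` — signed barometric pressure change, last minus first sample in
#'   the window (hPa).  Pressure falls with altitude, so `Pd` is negative
#'   while climbing upstairs and positive while going downstairs.
#' * `Pdabs` — `|Pd|`, which flags stair climbing in either direction.
#' * `Xmeans`, `Ymeans`, `Zmeans` — per-axis arithmetic means of the raw
#'   accelerometer samples, gravity included (m/s^2).  For a phone carried
#'   upright in a trouser pocket gravity loads mostly the Y axis, so
#'   `Ymeans` drops when the wearer sits.
#' * `Twave` — motion wave: the sum over consecutive samples of the
#'   Euclidean norm of the tri-axial acceleration difference (m/s^2).  It
#'   orders motion intensity: standing < walking < running.
#'
#' @param window a `sensor_window` from [window_stream()].
#' @return [pressure_difference()], [pressure_difference_abs()] and
#'   [twave()] return a single numeric; [axis_means()] a named numeric
#'   `c(Xmeans=, Ymeans=, Zmeans=)`; [extract_features()] a named numeric
#'   of all six features.
#' @name features
NULL

#' @rdname features
#' @export
pressure_difference <- function(window) {
  p <- window$pressure$p
  if (length(p) < 2) {
    har_error("pressure difference undefined: window has fewer than 2 pressure samples",
              "har_feature_undefined")
  }
  p[length(p)] - p[1]
}

#' @rdname features
#' @export
pressure_difference_abs <- function(window) {
  abs(pressure_difference(window))
}

#' @rdname features
#' @export
axis_means <- function(window) {
  a <- window$accel
  if (nrow(a) < 1) {
    har_error("axis means undefined: window has no accelerometer samples",
              "har_feature_undefined")
  }
  c(Xmeans = mean(a$ax), Ymeans = mean(a$ay), Zmeans = mean(a$az))
}

#' @rdname features
#' @export
twave <- function(window) {
  a <- window$accel
  if (nrow(a) < 2) {
    har_error("twave undefined: window has fewer than 2 accelerometer samples",
              "har_feature_undefined")
  }
  d <- diff(as.matrix(a[, c("ax", "ay", "az")]))
  sum(sqrt(rowSums(d^2)))
}

#' @rdname features
#' @param impute_pressure if `TRUE` (default) a window with fewer than two
#'   pressure samples gets `Pd = Pdabs = 0` (with a warning) instead of an
#'   error, so accelerometer-only streams remain classifiable on the
#'   flat-ground part of the tree.
#' @param warn if `FALSE`, suppress the imputation warning (used by
#'   [feature_table()], which warns once per table instead).
#' @export
extract_features <- function(window, impute_pressure = TRUE, warn = TRUE) {
  if (length(window$pressure$p) >= 2) {
    pd <- pressure_difference(window)
  } else if (impute_pressure) {
    if (warn) warning("window has no usable pressure samples; imputing Pd = Pdabs = 0")
    pd <- 0
  } else {
    har_error("Pd undefined: window has fewer than 2 pressure samples",
              "har_feature_undefined")
  }
  am <- axis_means(window)
  c(Pd = pd, Pdabs = abs(pd), am, Twave = twave(window))
}

#' Feature table for a list of windows
#'
#' @param windows list of windows from [window_stream()].
#' @param impute_pressure see [extract_features()]; if any window lacks
#'   pressure a single warning is emitted for the whole table.
#' @return data.frame with columns
#'   `t_start, Pd, Pdabs, Xmeans, Ymeans, Zmeans, Twave, label`.
#' @export
feature_table <- function(windows, impute_pressure = TRUE) {
  har_assert(length(windows) > 0, "no windows to extract features from",
             "har_empty_stream")
  missing_p <- vapply(windows, function(w) length(w$pressure$p) < 2, logical(1))
  if (impute_pressure && any(missing_p)) {
    warning(sprintf("%d window(s) lack pressure samples; imputing Pd = Pdabs = 0",
                    sum(missing_p)))
  }
  rows <- lapply(windows, function(w) {
    fv <- extract_features(w, impute_pressure = impute_pressure, warn = FALSE)
    data.frame(t_start = w$t_start, as.list(fv), label = w$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname feature_table
#' @param x a feature table.
#' @param path file path for the CSV
#'   (`t_start,Pd,Pdabs,Xmeans,Ymeans,Zmeans,Twave,label`).
#' @export
write_feature_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname feature_table
#' @export
read_feature_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_start", "Pd", "Pdabs", "Xmeans", "Ymeans", "Zmeans", "Twave")
  har_assert(all(need %in% names(d)),
             "feature CSV must have columns t_start,Pd,Pdabs,Xmeans,Ymeans,Zmeans,Twave[,label]")
  d
}

# The six feature names, in canonical column order.
FEATURE_NAMES <- c("Pd", "Pdabs", "Xmeans", "Ymeans", "Zmeans", "Twave")
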