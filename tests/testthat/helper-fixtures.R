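# Shared fixtures, all generated in code.

# A stream of n samples at rate_hz with constant acceleration and pressure.
constant_stream <- function(n, rate_hz, axyz = c(0, 9.81, 0), p = 1013.25,
                            labels = NULL) {
  t <- (seq_len(n) - 1) / rate_hz
  sensor_stream(data.frame(t = t, ax = axyz[1], ay = axyz[2], az = axyz[3]),
                data.frame(t = t, p = p),
                labels = labels, rate_hz = rate_hz)
}

# Build a single window directly from sample vectors (1 Hz spacing).
mk_window <- function(ax, ay = ax, az = ax, p = NULL, rate_hz = 1) {
  t <- (seq_along(ax) - 1) / rate_hz
  pressure <- if (is.null(p)) data.frame(t = numeric(0), p = numeric(0)) else
    data.frame(t = (seq_along(p) - 1) / rate_hz, p = p)
  structure(list(t_start = 0, duration = length(ax) / rate_hz,
                 accel = data.frame(t = t, ax = ax, ay = ay, az = az),
                 pressure = pressure, label = NA_character_),
            class = "sensor_window")
}

# Memoised 1 Hz / 5 s training feature table (90 windows, six activities).
.fixture_cache <- new.env(parent = emptyenv())
training_features_1hz <- function(seed = 42) {
  key <- paste0("tf", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synthetic_config(rate_hz = 1, seed = seed)
    .fixture_cache[[key]] <- feature_table(generate_training_set(cfg, 15, 5))
  }
  .fixture_cache[[key]]
}

activity_names <- function() names(default_activity_params())
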