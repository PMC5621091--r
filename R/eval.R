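#' Confusion matrix and per-class / macro accuracy
#'
#' Per-class accuracy is the diagonal over the row sum (recall); the
#' average ("macro") accuracy is the unweighted mean of per-class
#' accuracies, so rare classes count as much as common ones.
#'
#' @param truth ground-truth labels.
#' @param predicted predicted labels, same length.
#' @param classes class ordering for the matrix; defaults to the sorted
#'   union of both label sets.
#' @return A `har_eval`: list with `confusion` (rows = truth, columns =
#'   prediction), `per_class` (named accuracies), `macro_accuracy`, `n`.
#' @export
evaluate <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    har_error(sprintf("length mismatch: %d truth vs %d predicted labels",
                      length(truth), length(predicted)), "har_param_error")
  }
  if (is.null(classes)) classes <- sort(union(truth, predicted))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  row_tot <- rowSums(cm)
  per_class <- ifelse(row_tot > 0, diag(cm) / row_tot, NA_real_)
  names(per_class) <- classes
  structure(list(confusion = cm, per_class = per_class,
                 macro_accuracy = mean(per_class, na.rm = TRUE),
                 n = length(truth)),
            class = "har_eval")
}

#' @export
print.har_eval <- function(x, ...) {
  cat("<har_eval>\n")
  print(x$confusion)
  cat("per-class accuracy:\n")
  print(round(x$per_class, 4))
  cat(sprintf("macro (average) accuracy: %.4f over %d windows\n",
              x$macro_accuracy, x$n))
  invisible(x)
}

#' Pipeline configuration
#'
#' The three parameters that drive both power draw and accuracy are the
#' sampling rate, the window length, and the smoothing half-window `k`;
#' the rest tune the tree builder.
#'
#' @param rate_hz sampling rate the pipeline runs at (streams are
#'   decimated to it), Hz.
#' @param window_s window length, seconds.
#' @param overlap_s window overlap, seconds.
#' @param k smoothing half-window ([smooth_sequence()]).
#' @param purity_threshold,svm_cost,m_top,full_powerset see [train_tree()].
#' @param seed integer seed for training.
#' @param costs feature-cost table ([default_feature_costs()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rate_hz = 1, window_s = 5, overlap_s = 0, k = 1,
                            purity_threshold = 0.95, svm_cost = 1,
                            m_top = 4, full_powerset = FALSE,
                            seed = 1L, costs = default_feature_costs()) {
  har_assert(rate_hz > 0 && window_s > overlap_s && overlap_s >= 0 && k >= 0,
             "invalid pipeline parameters")
  structure(list(rate_hz = rate_hz, window_s = window_s, overlap_s = overlap_s,
                 k = as.integer(k), purity_threshold = purity_threshold,
                 svm_cost = svm_cost, m_top = m_top,
                 full_powerset = full_powerset,
                 seed = as.integer(seed), costs = costs),
            class = "pipeline_config")
}

stream_to_features <- function(stream, config, stage) {
  w <- tryCatch(window_stream(stream, config$window_s, config$overlap_s),
                error = function(e) har_error(
                  sprintf("[%s/windowing] %s", stage, conditionMessage(e)),
                  "har_stage_error"))
  tryCatch(feature_table(w),
           error = function(e) har_error(
             sprintf("[%s/features] %s", stage, conditionMessage(e)),
             "har_stage_error"))
}

#' Run the full recognition pipeline
#'
#' Decimates both streams to the configured rate, windows them, extracts
#' features, trains the hierarchical SVM on the labelled training stream,
#' classifies the test windows, smooths the prediction sequence, and
#' evaluates raw and smoothed predictions against the test windows'
#' majority labels.
#'
#' @param train_stream labelled [sensor_stream()] used for training, or a
#'   list of pre-cut labelled windows (e.g. from
#'   [generate_training_set()]).
#' @param test_stream labelled [sensor_stream()] to classify.
#' @param config a [pipeline_config()].
#' @param verbose if `TRUE`, log each stage's parameters and shapes.
#' @return A `har_pipeline`: list with `tree`, `predictions` (data.frame
#'   `t_start, truth, raw, smoothed`), `raw_eval`, `smoothed_eval`,
#'   `improvement` (per class and macro: smoothed minus raw accuracy), and
#'   `config`.
#' @export
run_pipeline <- function(train_stream, test_stream, config = pipeline_config(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (inherits(train_stream, "sensor_stream")) {
    if (abs(train_stream$rate_hz - config$rate_hz) > 1e-9) {
      train_stream <- decimate(train_stream, config$rate_hz)
    }
    train_feats <- stream_to_features(train_stream, config, "train")
  } else {
    train_feats <- feature_table(train_stream)   # pre-cut windows
  }
  say("training features: %d windows x %d classes",
      nrow(train_feats), length(unique(train_feats$label)))
  tree <- tryCatch(
    train_tree(train_feats, costs = config$costs, seed = config$seed,
               purity_threshold = config$purity_threshold,
               cost = config$svm_cost, m_top = config$m_top,
               full_powerset = config$full_powerset),
    error = function(e) har_error(
      sprintf("[train/tree] %s", conditionMessage(e)), "har_stage_error"))
  say("tree: %d nodes over %s", tree$n_nodes, paste(tree$classes, collapse = ", "))
  if (abs(test_stream$rate_hz - config$rate_hz) > 1e-9) {
    test_stream <- decimate(test_stream, config$rate_hz)
  }
  test_feats <- stream_to_features(test_stream, config, "test")
  raw <- predict(tree, test_feats)
  smoothed <- as.character(smooth_sequence(raw, config$k))
  say("classified %d test windows (k = %d)", length(raw), config$k)
  truth <- test_feats$label
  raw_eval <- evaluate(truth, raw, classes = tree$classes)
  smoothed_eval <- evaluate(truth, smoothed, classes = tree$classes)
  improvement <- list(
    per_class = smoothed_eval$per_class - raw_eval$per_class,
    macro = smoothed_eval$macro_accuracy - raw_eval$macro_accuracy)
  structure(list(tree = tree,
                 predictions = data.frame(t_start = test_feats$t_start,
                                          truth = truth, raw = raw,
                                          smoothed = smoothed,
                                          stringsAsFactors = FALSE),
                 raw_eval = raw_eval, smoothed_eval = smoothed_eval,
                 improvement = improvement, config = config),
            class = "har_pipeline")
}

#' @export
print.har_pipeline <- function(x, ...) {
  cat(sprintf("<har_pipeline> %g Hz / %g s windows / k = %d\n",
              x$config$rate_hz, x$config$window_s, x$config$k))
  cat(sprintf("raw macro accuracy:      %.4f\n", x$raw_eval$macro_accuracy))
  cat(sprintf("smoothed macro accuracy: %.4f (improvement %+.4f)\n",
              x$smoothed_eval$macro_accuracy, x$improvement$macro))
  invisible(x)
}

#' Accuracy across sampling rates
#'
#' Runs the pipeline at several sampling rates, decimating the same
#' high-rate training and test streams to each, to check that a low rate
#' with the same window length retains the accuracy of a Nyquist-abiding
#' one.
#'
#' @param train_stream,test_stream labelled high-rate [sensor_stream()]s;
#'   every rate in `rates` must divide their rate evenly.
#' @param rates sampling rates (Hz) to evaluate.
#' @param config base [pipeline_config()]; `rate_hz` is overridden per run.
#' @return data.frame with columns `rate_hz`, `macro_raw`,
#'   `macro_smoothed`.
#' @export
rate_sweep <- function(train_stream, test_stream, rates = c(1, 5, 10, 50),
                       config = pipeline_config()) {
  rows <- lapply(rates, function(r) {
    cfg <- config
    cfg$rate_hz <- r
    res <- run_pipeline(train_stream, test_stream, cfg)
    data.frame(rate_hz = r,
               macro_raw = res$raw_eval$macro_accuracy,
               macro_smoothed = res$smoothed_eval$macro_accuracy)
  })
  do.call(rbind, rows)
}
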