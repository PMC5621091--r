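# Mode correction of one buffer: keep the centre label if it is among the
# modes, otherwise replace it with the primary mode (the tied mode that
# occurs earliest in the buffer).
mode_correct <- function(buffer, center) {
  counts <- table(buffer)
  modes <- names(counts)[counts == max(counts)]
  if (buffer[center] %in% modes) return(buffer[center])
  buffer[match(TRUE, buffer %in% modes)]
}

#' Context-based label smoothing
#'
#' Activities are continuous, so an isolated window prediction that
#' disagrees with its neighbourhood is probably wrong.  The smoother
#' corrects each raw prediction using the mode of a sliding window of
#' length `2k + 1` centred on it: the centre label is kept when it belongs
#' to the set of modes, otherwise it is replaced by the primary mode
#' (under ties, the tied label occurring earliest in the buffer).
#'
#' `smooth_sequence()` returns one label per input position.  The first
#' `k` positions are emitted raw (warm-up: no full neighbourhood exists
#' yet), interior positions use the full `2k + 1` window, and the final
#' `k` positions are corrected with progressively truncated windows so the
#' output length equals the input length.  The correction of position `t`
#' is only available once `t + k` inputs have been seen: the method has an
#' inherent reporting delay of `k` windows, exposed as the `delay`
#' attribute rather than hidden by shifting timestamps.
#'
#' @param results character vector of raw window predictions, in time
#'   order.
#' @param k half-window (delay) in windows; `k = 0` is the identity.
#' @return Character vector of corrected labels, same length as the input,
#'   with attribute `delay = k`.
#' @export
smooth_sequence <- function(results, k) {
  har_assert(is.numeric(k) && length(k) == 1 && k >= 0 && k == round(k),
             "`k` must be a non-negative integer")
  results <- as.character(results)
  n <- length(results)
  k <- as.integer(k)
  if (k == 0L || n == 0L) return(structure(results, delay = 0L))
  out <- results
  for (t in seq_len(n)) {
    if (t <= k) next                       # warm-up: raw
    hi <- min(t + k, n)                    # truncated at end of stream
    buf <- results[(t - k):hi]
    out[t] <- mode_correct(buf, k + 1L)
  }
  structure(out, delay = k)
}

#' @rdname smooth_sequence
#' @return `smoother_state()` returns the initial state for online use
#'   with [smooth_step()].
#' @export
smoother_state <- function(k) {
  har_assert(is.numeric(k) && length(k) == 1 && k >= 0 && k == round(k),
             "`k` must be a non-negative integer")
  structure(list(k = as.integer(k), buffer = character(0), n_seen = 0L),
            class = "smoother_state")
}

#' Online smoothing, one raw label at a time
#'
#' Feed raw predictions as they arrive.  While fewer than `2k + 1` labels
#' have been seen the raw label is emitted unchanged (warm-up); from the
#' `2k + 1`-th input on, each step emits the corrected label for the
#' centre of the current buffer — i.e. the correction for the window seen
#' `k` steps ago.  After the stream ends, [smoother_flush()] emits the
#' corrections for the final `k` positions using progressively truncated
#' buffers.
#'
#' @param state a `smoother_state`.
#' @param r the next raw label.
#' @return `smooth_step()` returns `list(state = <updated state>,
#'   emitted = <label>)`; `smoother_flush()` returns a character vector of
#'   up to `k` labels.
#' @export
smooth_step <- function(state, r) {
  har_assert(inherits(state, "smoother_state"), "`state` must be a smoother_state")
  k <- state$k
  width <- 2L * k + 1L
  state$buffer <- c(state$buffer, as.character(r))
  if (length(state$buffer) > width) {
    state$buffer <- state$buffer[-1L]
  }
  state$n_seen <- state$n_seen + 1L
  emitted <- if (state$n_seen < width) {
    as.character(r)                        # warm-up: raw
  } else {
    mode_correct(state$buffer, k + 1L)
  }
  list(state = state, emitted = emitted)
}

#' @rdname smooth_step
#' @export
smoother_flush <- function(state) {
  har_assert(inherits(state, "smoother_state"), "`state` must be a smoother_state")
  k <- state$k
  if (k == 0L || state$n_seen == 0L) return(character(0))
  n_tail <- min(k, max(state$n_seen - k - 1L, 0L))
  if (state$n_seen < 2L * k + 1L) {
    # Short stream: every position past the warm-up still owes a correction.
    n_tail <- max(state$n_seen - k, 0L)
  }
  buf <- state$buffer
  m <- length(buf)
  out <- character(0)
  # Remaining uncorrected positions are the last n_tail of the buffer.
  for (i in seq_len(n_tail)) {
    start <- m - n_tail + i - k
    window <- buf[max(start, 1L):m]
    center <- (m - n_tail + i) - max(start, 1L) + 1L
    out <- c(out, mode_correct(window, center))
  }
  out
}

#' Closed-form accuracy of sliding-window majority voting
#'
#' Assume each raw window prediction is independently wrong with
#' probability `psi`.  Majority correction over a window of `2k + 1`
#' predictions yields the right label whenever at most `k` of them are
#' wrong, so the corrected per-window accuracy is the binomial tail
#' `sum_{i=0..k} C(2k+1, i) psi^i (1-psi)^(2k+1-i)`.  At `k = 0` this is
#' `1 - psi`; for `psi < 0.5` it increases with `k`.
#'
#' @param psi per-window error probability, in `[0, 1]`.
#' @param k half-window size (non-negative integer); vectorised over `k`.
#' @return Corrected accuracy in `[0, 1]`.
#' @export
majority_accuracy <- function(psi, k) {
  har_assert(is.numeric(psi) && all(psi >= 0 & psi <= 1),
             "`psi` must be a probability in [0, 1]")
  har_assert(all(k >= 0 & k == round(k)), "`k` must be a non-negative integer")
  pbinom(k, 2 * k + 1, psi)
}

#' Choose the smoothing half-window from the accuracy model
#'
#' Larger `k` improves the corrected accuracy but adds `k` windows of
#' reporting delay.  This picks the smallest `k` at which the marginal
#' accuracy gain of one more step falls below `min_gain`: the point where
#' extra delay stops paying for itself.  With the defaults
#' (`min_gain = 0.05`, `k_max = 5`) and realistic error rates
#' (`psi` roughly 0.05-0.3) this selects `k = 1`, i.e. a window of 3.
#'
#' @param psi per-window error probability, in `(0, 0.5)`; majority voting
#'   is not beneficial at 0.5 or above.
#' @param min_gain minimum accuracy improvement that justifies one more
#'   window of delay (default 0.05).
#' @param k_max largest half-window considered (default 5).
#' @return The selected half-window `k`.
#' @export
choose_k <- function(psi, min_gain = 0.05, k_max = 5) {
  har_assert(is.numeric(psi) && length(psi) == 1 && psi > 0,
             "`psi` must be a single probability in (0, 0.5)")
  if (psi >= 0.5) {
    har_error("majority voting is not beneficial for psi >= 0.5", "har_param_error")
  }
  for (k in 0:(k_max - 1)) {
    gain <- majority_accuracy(psi, k + 1) - majority_accuracy(psi, k)
    if (gain < min_gain) return(k)
  }
  k_max
}

#' Tabulate the majority-vote accuracy model
#'
#' Convenience table of corrected accuracy over a grid of error
#' probabilities and half-window sizes, mirroring how the model is used to
#' pick the smoothing window.
#'
#' @param psi vector of per-window error probabilities.
#' @param k vector of half-window sizes.
#' @return data.frame with columns `psi`, `k`, `window` (`2k+1`),
#'   `accuracy`.
#' @export
accuracy_model_table <- function(psi = c(0.3, 0.2, 0.1, 0.05), k = 0:5) {
  grid <- expand.grid(psi = psi, k = k)
  grid$window <- 2 * grid$k + 1
  grid$accuracy <- mapply(majority_accuracy, grid$psi, grid$k)
  grid[order(grid$psi, grid$k), ]
}
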