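#' Cut a trace into scaled sliding windows
#'
#' Windows start every `stride` samples; there are
#' `floor((n - window_len)/stride) + 1` of them. Each window is min-max
#' scaled independently (a constant window maps to zeros), which makes the
#' classifier blind to the absolute scale and offset of the recording.
#' Positive-polarity traces are sign-flipped before scaling so the classifier
#' always sees negative-going events (direction normalisation; the same
#' convention as [make_training_set()]).
#'
#' @param x a `mini_trace`.
#' @param window_len window length in samples (default 600).
#' @param stride step between window starts in samples (default 20).
#' @return matrix (n_windows x window_len) of scaled windows; attribute
#'   `starts` holds the 1-based start sample of each window.
#' @export
window_trace <- function(x, window_len = 600L, stride = 20L) {
  stopifnot(inherits(x, "mini_trace"), stride >= 1)
  n <- length(x$samples)
  if (n < window_len)
    stop(sprintf("trace has %d samples, shorter than one window (%d)",
                 n, window_len))
  starts <- seq(1L, n - window_len + 1L, by = stride)
  src <- if (x$polarity == "positive") -x$samples else x$samples
  W <- matrix(0, length(starts), window_len)
  for (i in seq_along(starts))
    W[i, ] <- minmax_scale(src[starts[i]:(starts[i] + window_len - 1L)])
  attr(W, "starts") <- starts
  W
}

#' Sliding-window classifier inference over a whole trace
#'
#' Runs the classifier over every window position at the given stride and
#' resamples the stride-resolution scores back to the sampling rate of the
#' raw data (nearest-neighbour hold, which preserves the [0, 1] range and
#' peak heights; leading/trailing samples take the nearest computed score).
#'
#' Windowing and inference proceed in chunks so memory stays bounded on long
#' recordings.
#'
#' @param model a trained `event_classifier`.
#' @param x a `mini_trace`.
#' @param stride stride in samples (default 20).
#' @param batch_size windows per inference batch.
#' @return object of class `prediction_trace`: list with `values` (length of
#'   the trace, in [0, 1]), `scores` (stride resolution), `starts` (window
#'   start samples), `stride`, `window_len`.
#' @export
predict_trace <- function(model, x, stride = 20L, batch_size = 1024L) {
  stopifnot(inherits(model, "event_classifier"), inherits(x, "mini_trace"))
  n <- length(x$samples)
  wl <- model$spec$window_len
  if (n < wl)
    stop(sprintf("trace has %d samples, shorter than one model window (%d)",
                 n, wl))
  starts <- seq(1L, n - wl + 1L, by = stride)
  src <- if (x$polarity == "positive") -x$samples else x$samples
  scores <- numeric(length(starts))
  for (chunk_start in seq(1L, length(starts), by = batch_size)) {
    idx <- chunk_start:min(length(starts), chunk_start + batch_size - 1L)
    W <- matrix(0, length(idx), wl)
    for (j in seq_along(idx)) {
      s <- starts[idx[j]]
      W[j, ] <- minmax_scale(src[s:(s + wl - 1L)])
    }
    scores[idx] <- predict(model, W, batch_size = batch_size)
  }
  values <- rep(scores, each = stride)[seq_len(min(n, length(scores) * stride))]
  if (length(values) < n) values <- c(values, rep(scores[length(scores)],
                                                  n - length(values)))
  structure(list(values = values, scores = scores, starts = starts,
                 stride = as.integer(stride), window_len = wl, n = n),
            class = "prediction_trace")
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat(sprintf("<prediction_trace> %d positions (stride %d), max score %.3f\n",
              length(x$scores), x$stride, max(x$scores)))
  invisible(x)
}

#' Localise events from a prediction trace
#'
#' A running maximum filter is applied to the stride-resolution scores; runs
#' of filtered scores at or above `min_height` lasting at least `min_width`
#' strides are events. For each event the raw data following the threshold
#' crossing is searched for the steepest rise: the extremum of the first
#' derivative of the (lightly smoothed) segment, minimum for negative
#' polarity, maximum for positive.
#'
#' @param pred a `prediction_trace`.
#' @param x the `mini_trace` the prediction was computed from.
#' @param min_height peak threshold on the prediction trace, in (0, 1).
#' @param min_width minimum peak width in strides (default 5; the synthetic
#'   benchmark uses 10).
#' @param maxfilt_width maximum-filter width in strides (default 5).
#' @param smooth_samples Hann length for the trough/derivative search;
#'   defaults to the rate-scaled analysis filter (20 points at 50 kHz).
#' @param back_ms how far before the event trough the steepest rise is
#'   searched (default 2 ms; peak latency for millisecond-decay events is ~0.3 ms).
#' @return data.frame with one row per event: `threshold_crossing_idx`,
#'   `steepest_rise_idx` (1-based sample indices), `peak_confidence`.
#' @export
locate_events <- function(pred, x, min_height = 0.5, min_width = 5L,
                          maxfilt_width = 5L,
                          smooth_samples = hann_points_for_rate(x$sampling_rate),
                          back_ms = 2) {
  stopifnot(inherits(pred, "prediction_trace"), inherits(x, "mini_trace"))
  if (min_height <= 0 || min_height >= 1)
    stop("min_height must be in (0, 1)")
  filt <- max_filter(pred$scores, maxfilt_width)
  above <- filt >= min_height
  if (!any(above))
    return(data.frame(threshold_crossing_idx = integer(),
                      steepest_rise_idx = integer(),
                      peak_confidence = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts_rle <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_width)
  # the max filter widens any region by (maxfilt_width - 1); a run passes the
  # width criterion only if its raw above-threshold support accounts for
  # that, otherwise a few isolated high scores would masquerade as a peak of
  # the required width
  min_support <- max(1L, min_width - maxfilt_width + 1L)
  keep <- keep[vapply(keep, function(k)
    sum(pred$scores[starts_rle[k]:ends[k]] >= min_height) >= min_support,
    logical(1))]
  if (!length(keep))
    return(data.frame(threshold_crossing_idx = integer(),
                      steepest_rise_idx = integer(),
                      peak_confidence = numeric()))
  back <- max(2L, round(back_ms / 1000 * x$sampling_rate))
  out <- lapply(keep, function(k) {
    i0 <- starts_rle[k]; i1 <- ends[k]
    crossing <- pred$starts[i0]
    conf <- max(pred$scores[i0:i1])
    # anchor the raw-data search at the run's confidence maximum: the run can
    # begin up to a window before the event (the classifier responds while
    # the event is anywhere in its input), but confidence peaks with the
    # event inside the window, so [anchor, anchor + window) brackets it
    anchor <- pred$starts[i0 + which.max(pred$scores[i0:i1]) - 1L]
    seg_end <- min(length(x$samples), anchor + pred$window_len - 1L)
    seg <- x$samples[anchor:seg_end]
    ys <- hann_smooth(seg, smooth_samples)
    if (x$polarity == "positive") ys <- -ys
    # two-step: find the (smoothed) event trough, then the steepest rise in
    # the few ms before it — far more robust at low SNR than a derivative
    # extremum over the whole segment
    trough <- which.min(ys)
    lo <- max(1L, trough - back)
    if (trough - lo < 1)
      return(data.frame(threshold_crossing_idx = crossing,
                        steepest_rise_idx = anchor + trough - 1L,
                        peak_confidence = conf))
    d <- diff(ys[lo:trough])
    rise_rel <- lo + which.min(d) - 1L
    data.frame(threshold_crossing_idx = crossing,
               steepest_rise_idx = anchor + rise_rel - 1L,
               peak_confidence = conf)
  })
  do.call(rbind, out)
}

#' Detect events in a trace with a trained classifier
#'
#' Convenience wrapper chaining [predict_trace()] and [locate_events()].
#'
#' @inheritParams predict_trace
#' @inheritParams locate_events
#' @return as [locate_events()], with the event time in seconds added as
#'   `time_s` (steepest-rise sample / sampling rate).
#' @export
detect_events <- function(model, x, stride = 20L, min_height = 0.5,
                          min_width = 5L, maxfilt_width = 5L,
                          batch_size = 1024L) {
  pred <- predict_trace(model, x, stride = stride, batch_size = batch_size)
  ev <- locate_events(pred, x, min_height = min_height, min_width = min_width,
                      maxfilt_width = maxfilt_width)
  ev$time_s <- (ev$steepest_rise_idx - 1) / x$sampling_rate
  attr(ev, "prediction") <- pred
  ev
}
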