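#' Match detected event times against ground truth
#'
#' Greedy one-to-one matching: candidate (truth, detection) pairs within the
#' tolerance are sorted by absolute time difference and assigned in order,
#' each truth event and each detection being used at most once. Unmatched
#' detections count as false positives, unmatched truth events as false
#' negatives.
#'
#' @param detected_times numeric vector of detected event times, seconds.
#' @param truth_times numeric vector of true onset times, seconds.
#' @param tolerance_s matching tolerance in seconds (default 2 ms).
#' @return list with `TP`, `FP`, `FN` and a data.frame `matches`
#'   (truth_idx, detected_idx, dt_s).
#' @export
match_to_truth <- function(detected_times, truth_times, tolerance_s = 0.002) {
  stopifnot(tolerance_s > 0)
  nd <- length(detected_times); nt <- length(truth_times)
  if (!nd || !nt) {
    return(list(TP = 0L, FP = nd, FN = nt,
                matches = data.frame(truth_idx = integer(),
                                     detected_idx = integer(),
                                     dt_s = numeric())))
  }
  dmat <- abs(outer(truth_times, detected_times, "-"))
  cand <- which(dmat <= tolerance_s, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(list(TP = 0L, FP = nd, FN = nt,
                matches = data.frame(truth_idx = integer(),
                                     detected_idx = integer(),
                                     dt_s = numeric())))
  }
  ord <- order(dmat[cand])
  cand <- cand[ord, , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  mt <- integer(0); md <- integer(0); dts <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    ti <- cand[i, 1]; di <- cand[i, 2]
    if (used_t[ti] || used_d[di]) next
    used_t[ti] <- TRUE; used_d[di] <- TRUE
    mt <- c(mt, ti); md <- c(md, di); dts <- c(dts, dmat[ti, di])
  }
  list(TP = length(mt), FP = nd - length(mt), FN = nt - length(mt),
       matches = data.frame(truth_idx = mt, detected_idx = md, dt_s = dts))
}

#' Precision, recall, and F1 from confusion counts
#'
#' Conventions for zero denominators: if TP = FP = FN = 0 (nothing to detect,
#' nothing detected) all three metrics are 1; otherwise any undefined ratio
#' is 0.
#'
#' @param TP,FP,FN non-negative counts.
#' @return one-row data.frame: TP, FP, FN, precision, recall, f1.
#' @export
detection_metrics <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP == 0 && FP == 0 && FN == 0) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (TP + FP > 0) TP / (TP + FP) else 0
    recall <- if (TP + FN > 0) TP / (TP + FN) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  data.frame(TP = TP, FP = FP, FN = FN, precision = precision,
             recall = recall, f1 = f1)
}

#' Score a set of detected times against ground truth
#'
#' @param detected_times detected event times, seconds.
#' @param truth ground-truth data.frame from [place_events()] (or a numeric
#'   vector of onset times).
#' @param tolerance_s matching tolerance, seconds.
#' @return one-row data.frame as [detection_metrics()].
#' @export
score_detection <- function(detected_times, truth, tolerance_s = 0.002) {
  tt <- if (is.data.frame(truth)) truth$onset_time_s else truth
  m <- match_to_truth(detected_times, tt, tolerance_s)
  detection_metrics(m$TP, m$FP, m$FN)
}

# ---------------------------------------------------------------------------
# Uniform detector interface: an `event_detector` is a list with
#   $detect(trace, threshold) -> numeric event times (s)
#   $default_threshold
# so the classifier and all baselines plug into the same scoring and sweep.

new_detector <- function(name, default_threshold, detect) {
  structure(list(name = name, default_threshold = default_threshold,
                 detect = detect),
            class = "event_detector")
}

#' Classifier-based detector with the benchmark interface
#'
#' Wraps a trained classifier; the scalar threshold is `min_height` on the
#' prediction trace. The prediction trace for the most recent input is cached
#' so threshold sweeps rerun only the cheap localisation step.
#'
#' @param model a trained `event_classifier`.
#' @param stride stride in samples.
#' @param min_width minimum peak width in strides (benchmark default 10).
#' @param default_threshold default `min_height` (0.5).
#' @return an `event_detector`.
#' @export
classifier_detector <- function(model, stride = 20L, min_width = 10L,
                                default_threshold = 0.5) {
  cache <- new.env(parent = emptyenv())
  detect <- function(x, threshold = default_threshold) {
    key <- c(length(x$samples), sum(x$samples))
    if (is.null(cache$key) || !identical(cache$key, key)) {
      cache$pred <- predict_trace(model, x, stride = stride)
      cache$key <- key
    }
    thr <- min(max(threshold, 1e-6), 1 - 1e-6)
    ev <- locate_events(cache$pred, x, min_height = thr, min_width = min_width)
    if (is.null(ev) || !nrow(ev)) return(numeric(0))
    (ev$steepest_rise_idx - 1) / x$sampling_rate
  }
  new_detector("classifier", default_threshold, detect)
}

#' Template-matching detector with the benchmark interface
#' @param template template waveform (see [event_template()]).
#' @param default_threshold detection criterion threshold (default -4).
#' @return an `event_detector`.
#' @export
template_detector <- function(template, default_threshold = -4) {
  detect <- function(x, threshold = default_threshold) {
    r <- template_matching_detect(x, template, criterion_threshold = threshold)
    (r$event_indices - 1) / x$sampling_rate
  }
  new_detector("template_matching", default_threshold, detect)
}

#' Deconvolution detector with the benchmark interface
#' @param template template waveform.
#' @param default_threshold threshold in SDs of the detection trace (5).
#' @return an `event_detector`.
#' @export
deconvolution_detector <- function(template, default_threshold = 5) {
  detect <- function(x, threshold = default_threshold) {
    r <- deconvolution_detect(x, template, threshold_sd_mult = threshold)
    (r$event_indices - 1) / x$sampling_rate
  }
  new_detector("deconvolution", default_threshold, detect)
}

#' Finite-threshold detector with the benchmark interface
#' @param default_threshold amplitude threshold in signal units (-4).
#' @return an `event_detector`.
#' @export
threshold_detector <- function(default_threshold = -4) {
  detect <- function(x, threshold = default_threshold) {
    r <- finite_threshold_detect(x, amp_threshold = threshold)
    (r$event_indices - 1) / x$sampling_rate
  }
  new_detector("finite_threshold", default_threshold, detect)
}

#' Threshold robustness sweep
#'
#' Reruns a detector with its scalar threshold scaled to a range of fractions
#' of the default value and records the detected event count and (when ground
#' truth is given) the F1 score at each fraction. A detector error at one
#' fraction yields an NA row; the sweep continues.
#'
#' @param detector an `event_detector`.
#' @param x a `mini_trace`.
#' @param truth optional ground truth (data.frame or onset-time vector).
#' @param fractions fractions of the default threshold, in percent
#'   (default 5 to 195 in steps of 10).
#' @param tolerance_s matching tolerance for F1.
#' @return data.frame: fraction_pct, threshold, n_detected, and TP/FP/FN/
#'   precision/recall/f1 when truth is given.
#' @export
threshold_sweep <- function(detector, x, truth = NULL,
                            fractions = seq(5, 195, by = 10),
                            tolerance_s = 0.002) {
  stopifnot(inherits(detector, "event_detector"))
  rows <- lapply(fractions, function(f) {
    thr <- detector$default_threshold * f / 100
    times <- tryCatch(detector$detect(x, thr), error = function(e) NULL)
    if (is.null(times)) {
      row <- data.frame(fraction_pct = f, threshold = thr, n_detected = NA_integer_)
      if (!is.null(truth))
        row <- cbind(row, detection_metrics(0, 0, 0)[, c("TP", "FP", "FN",
                      "precision", "recall", "f1")] * NA)
      return(row)
    }
    row <- data.frame(fraction_pct = f, threshold = thr,
                      n_detected = length(times))
    if (!is.null(truth))
      row <- cbind(row, score_detection(times, truth, tolerance_s))
    row
  })
  do.call(rbind, rows)
}
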