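#' Extract aligned event segments from a trace
#'
#' Each detected event is cut from the raw trace as a `window_len`-sample
#' segment with its steepest-rise point at a fixed offset (`rise_offset`,
#' default a quarter of the window), so segments stack into an aligned 2D
#' array. Within each segment the first derivative is searched for further
#' peaks: any derivative peak with prominence >= 0.25 of the largest spawns
#' an additional event (overlapping-event splitting). Duplicate steepest-rise
#' indices are merged. Events too close to either end of the trace are
#' returned truncated with `complete = FALSE` and should be excluded from
#' kinetics.
#'
#' @param x a `mini_trace`.
#' @param locations data.frame from [locate_events()] / [detect_events()]
#'   (needs a `steepest_rise_idx` column), sorted by index.
#' @param window_len segment length in samples (default 600).
#' @param rise_offset position of the steepest-rise point within the segment
#'   (default `window_len %/% 4`).
#' @param smooth_samples Hann length for the derivative search (default 5).
#' @param prominence_ratio relative prominence for splitting (default 0.25).
#' @return list of `event_segment` objects: list(samples, rise_offset,
#'   rise_idx, complete).
#' @export
align_events <- function(x, locations, window_len = 600L,
                         rise_offset = window_len %/% 4L,
                         smooth_samples = 5L, prominence_ratio = 0.25) {
  stopifnot(inherits(x, "mini_trace"))
  if (is.null(locations) || !nrow(locations)) return(list())
  n <- length(x$samples)
  sgn <- if (x$polarity == "negative") -1 else 1
  rises <- integer(0)
  merge_radius <- max(1L, round(0.001 * x$sampling_rate))   # 1 ms
  for (ri in sort(unique(locations$steepest_rise_idx))) {
    i0 <- max(1L, ri - rise_offset + 1L)
    i1 <- min(n, i0 + window_len - 1L)
    d <- sgn * diff(hann_smooth(x$samples[i0:i1], smooth_samples))
    pk <- find_peaks(d, min_height = 0)
    rises <- c(rises, ri)   # the located event is always kept
    if (!nrow(pk)) next
    # additional (overlapping) events: derivative peaks with relative
    # prominence >= prominence_ratio of the largest, a rise rate that is a
    # comparable fraction of the steepest, and clearly above the segment's
    # derivative noise floor — without the floor, noise ripples on the decay
    # would split every low-SNR event
    floor_h <- 4 * stats::mad(d)
    keep <- pk$prominence >= prominence_ratio * max(pk$prominence) &
      pk$height >= prominence_ratio * max(pk$height) &
      pk$height >= floor_h
    rises <- c(rises, i0 + pk$idx[keep] - 1L)
  }
  rises <- sort(unique(rises))
  # merge rises closer than 1 ms (duplicate localizations of one event)
  if (length(rises) > 1) {
    keep <- c(TRUE, diff(rises) >= merge_radius)
    rises <- rises[keep]
  }
  lapply(rises, function(ri) {
    i0 <- ri - rise_offset + 1L
    i1 <- i0 + window_len - 1L
    complete <- i0 >= 1L && i1 <= n
    seg <- x$samples[max(1L, i0):min(n, i1)]
    structure(list(samples = seg,
                   rise_offset = if (complete) rise_offset else ri - max(1L, i0) + 1L,
                   rise_idx = ri, complete = complete),
              class = "event_segment")
  })
}

#' Measure amplitude, kinetics, and charge of one event
#'
#' The segment is smoothed with a Hann window (`hann_points`; set to 1 for no
#' smoothing). The baseline is the mean over `baseline_window` samples ending
#' `baseline_gap` samples before the steepest-rise point. Amplitude is the
#' signed difference between the event peak (extremum after the rise point,
#' per polarity) and the baseline. The 10-90% rise time and the half-decay
#' time are read off the smoothed waveform with linear interpolation between
#' samples; charge integrates the baseline-subtracted segment from the event
#' onset (last baseline crossing before the steepest rise) to the end of the
#' segment (trapezoidal rule), in signal units times ms.
#'
#' @param segment an `event_segment` from [align_events()].
#' @param sampling_rate Hz.
#' @param polarity "negative" or "positive".
#' @param hann_points Hann filter length in samples; the default 20 is tuned
#'   for 50 kHz and should be scaled with the sampling rate (see
#'   [hann_points_for_rate()]).
#' @param baseline_window baseline length in samples (default 50).
#' @param baseline_gap samples between baseline end and rise point (default 10).
#' @return one-row data.frame: amplitude, rise_10_90_ms, half_decay_ms,
#'   charge, peak_idx (index within the segment), baseline, valid flags.
#' @export
measure_event <- function(segment, sampling_rate,
                          polarity = c("negative", "positive"),
                          hann_points = 20L, baseline_window = 50L,
                          baseline_gap = 10L) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(segment, "event_segment"), hann_points >= 1)
  dt_ms <- 1000 / sampling_rate
  y <- hann_smooth(segment$samples, hann_points)
  sgn <- if (polarity == "negative") -1 else 1
  ro <- segment$rise_offset
  b0 <- max(1L, ro - baseline_gap - baseline_window)
  b1 <- max(1L, ro - baseline_gap)
  baseline <- mean(y[b0:b1])
  if (all(segment$samples == 0))
    return(data.frame(amplitude = 0, rise_10_90_ms = NA_real_,
                      half_decay_ms = NA_real_, charge = 0,
                      peak_idx = NA_integer_, baseline = 0,
                      kinetics_valid = FALSE))
  # peak: extremum after the rise point
  search <- ro:length(y)
  rel <- sgn * (y[search] - baseline)
  peak_rel <- which.max(rel)
  peak_idx <- search[peak_rel]
  amp_mag <- rel[peak_rel]
  amplitude <- sgn * amp_mag
  cross_time <- function(idx_range, level, increasing) {
    # first crossing of `level` by rel[] over idx_range (indices into y)
    v <- sgn * (y[idx_range] - baseline)
    hit <- if (increasing) which(v >= level) else which(v <= level)
    if (!length(hit)) return(NA_real_)
    i <- hit[1]
    if (i == 1) return(idx_range[1] * dt_ms)
    v0 <- v[i - 1]; v1 <- v[i]
    frac <- if (v1 == v0) 0 else (level - v0) / (v1 - v0)
    (idx_range[i - 1] + frac) * dt_ms
  }
  # rising phase: walk back from the peak to the last sub-10% sample
  pre <- sgn * (y[seq_len(peak_idx)] - baseline)
  onset_idx <- {
    below <- which(pre[seq_len(peak_idx - 1)] <= 0)
    if (length(below)) max(below) else 1L
  }
  rise_range <- onset_idx:peak_idx
  t10 <- cross_time(rise_range, 0.1 * amp_mag, TRUE)
  t90 <- cross_time(rise_range, 0.9 * amp_mag, TRUE)
  rise_10_90 <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10
  # half decay: first 50% crossing after the peak
  decay_range <- peak_idx:length(y)
  t50 <- cross_time(decay_range, 0.5 * amp_mag, FALSE)
  half_decay <- if (is.na(t50)) NA_real_ else t50 - peak_idx * dt_ms
  # charge: trapezoid of the baseline-subtracted raw segment from onset
  z <- segment$samples[onset_idx:length(segment$samples)] - baseline
  charge <- sum((z[-1] + z[-length(z)]) / 2) * dt_ms
  data.frame(amplitude = amplitude, rise_10_90_ms = rise_10_90,
             half_decay_ms = half_decay, charge = charge,
             peak_idx = peak_idx, baseline = baseline,
             kinetics_valid = segment$complete && !is.na(rise_10_90) &&
               !is.na(half_decay))
}

#' Hann filter length scaled to the sampling rate
#'
#' The default 20-point filter assumes 50 kHz; other rates scale
#' proportionally (minimum 1 point).
#'
#' @param sampling_rate Hz.
#' @param base_points filter length at 50 kHz.
#' @return integer filter length.
#' @export
hann_points_for_rate <- function(sampling_rate, base_points = 20L) {
  max(1L, as.integer(round(base_points * sampling_rate / 50000)))
}

#' Quantify all events of a recording
#'
#' Runs [align_events()] + [measure_event()] over a detection result.
#'
#' @param x a `mini_trace`.
#' @param locations output of [detect_events()] / [locate_events()].
#' @param window_len segment length (default 600).
#' @param hann_points Hann length; default auto-scaled from the rate.
#' @param ... passed to [measure_event()].
#' @return data.frame with one row per event (columns of [measure_event()]
#'   plus `event_idx`, `position_s`, `score`).
#' @export
quantify_events <- function(x, locations, window_len = 600L,
                            hann_points = hann_points_for_rate(x$sampling_rate),
                            ...) {
  segs <- align_events(x, locations, window_len = window_len,
                       smooth_samples = max(5L, hann_points))
  if (!length(segs))
    return(data.frame(event_idx = integer(), position_s = numeric(),
                      amplitude = numeric(), rise_10_90_ms = numeric(),
                      half_decay_ms = numeric(), charge = numeric(),
                      score = numeric()))
  rows <- lapply(seq_along(segs), function(i) {
    m <- measure_event(segs[[i]], x$sampling_rate, polarity = x$polarity,
                       hann_points = hann_points, ...)
    cbind(data.frame(event_idx = i,
                     position_s = (segs[[i]]$rise_idx - 1) / x$sampling_rate),
          m)
  })
  ev <- do.call(rbind, rows)
  if (!is.null(locations$peak_confidence)) {
    # score of the nearest located event
    ev$score <- vapply(ev$position_s * x$sampling_rate + 1, function(p) {
      locations$peak_confidence[which.min(abs(locations$steepest_rise_idx - p))]
    }, numeric(1))
  } else ev$score <- NA_real_
  ev
}

#' Per-recording summary of event statistics
#'
#' @param stats data.frame of per-event measurements (needs amplitude,
#'   rise_10_90_ms, half_decay_ms, charge columns; NAs ignored).
#' @param duration recording duration in seconds (> 0).
#' @return one-row data.frame: n_events, frequency_hz, duration_s, and
#'   mean/median of each measurement.
#' @export
summarize_recording <- function(stats, duration) {
  stopifnot(duration > 0)
  n <- if (is.null(stats)) 0L else nrow(stats)
  agg <- function(col, f) {
    if (!n || is.null(stats[[col]])) return(NA_real_)
    v <- stats[[col]][!is.na(stats[[col]])]
    if (!length(v)) NA_real_ else f(v)
  }
  data.frame(
    n_events = n, frequency_hz = n / duration, duration_s = duration,
    mean_amplitude = agg("amplitude", mean),
    median_amplitude = agg("amplitude", stats::median),
    mean_rise_10_90_ms = agg("rise_10_90_ms", mean),
    median_rise_10_90_ms = agg("rise_10_90_ms", stats::median),
    mean_half_decay_ms = agg("half_decay_ms", mean),
    median_half_decay_ms = agg("half_decay_ms", stats::median),
    mean_charge = agg("charge", mean),
    median_charge = agg("charge", stats::median))
}
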