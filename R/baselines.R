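# Conventional matched-filter detectors used as comparison methods.

# rolling sum of x over windows of length m (result length n - m + 1)
rolling_sum <- function(x, m) {
  cs <- c(0, cumsum(x))
  cs[(m + 1):length(cs)] - cs[seq_len(length(cs) - m)]
}

# rolling inner product of x with template tpl via FFT convolution
rolling_dot <- function(x, tpl) {
  n <- length(x); m <- length(tpl)
  L <- stats::nextn(n + m - 1, 2)
  fx <- stats::fft(c(x, rep(0, L - n)))
  ft <- stats::fft(c(tpl, rep(0, L - m)))
  full <- Re(stats::fft(fx * Conj(ft), inverse = TRUE)) / L
  full[seq_len(n - m + 1)]
}

#' Build an event template for the matched-filter detectors
#'
#' A peak-normalised biexponential waveform; benchmark convention is the
#' average kinetics of the simulated events.
#'
#' @param tau_rise,tau_decay time constants, ms.
#' @param sampling_rate Hz.
#' @param duration_ms template duration (default covers rise + 6 decay taus).
#' @return numeric template with peak 1.
#' @export
event_template <- function(tau_rise = 0.2, tau_decay = 1.0, sampling_rate = 50000,
                           duration_ms = tau_rise * 8 + 6 * tau_decay) {
  biexp_kernel(tau_rise, tau_decay, dt = 1000 / sampling_rate,
               duration = duration_ms, normalize = TRUE)
}

# Turn a logical criterion-exceeded vector into one event per contiguous run,
# placed at the extremum of `score` within the run. Runs separated by less
# than `min_separation` samples are merged (refractory merging), keeping the
# stronger extremum.
runs_to_events <- function(exceeded, score, min_separation = 0L) {
  if (!any(exceeded)) return(integer(0))
  r <- rle(exceeded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ev <- vapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    idx[which.max(score[idx])]
  }, integer(1))
  if (min_separation > 0 && length(ev) > 1) {
    merged <- ev[1]
    for (e in ev[-1]) {
      last <- merged[length(merged)]
      if (e - last < min_separation) {
        if (score[e] > score[last]) merged[length(merged)] <- e
      } else merged <- c(merged, e)
    }
    ev <- merged
  }
  ev
}

#' Template-matching (sliding optimal-scaling) detection
#'
#' At every offset the template is fitted to the data by least squares with a
#' free scale and offset; the detection criterion is the fitted scale divided
#' by the standard error of the fit. Events are reported where the criterion
#' passes the threshold (<= threshold for negative polarity events with a
#' positive-going template; >= |threshold| for positive polarity), one event
#' per contiguous crossing, placed at the criterion extremum.
#'
#' @param x a `mini_trace`.
#' @param template numeric template waveform (peak-normalised, positive).
#' @param criterion_threshold detection criterion threshold (default -4).
#' @return list of class `detector_result`: `detection_trace` (criterion at
#'   each offset), `event_indices` (sample index of the criterion extremum
#'   per event), `threshold_used`.
#' @export
template_matching_detect <- function(x, template, criterion_threshold = -4) {
  stopifnot(inherits(x, "mini_trace"))
  y <- x$samples
  n <- length(y); m <- length(template)
  if (m >= n) stop("template must be shorter than the trace")
  sum_t <- sum(template); sum_t2 <- sum(template^2)
  denom <- sum_t2 - sum_t^2 / m
  sy <- rolling_sum(y, m)
  sy2 <- rolling_sum(y^2, m)
  sty <- rolling_dot(y, template)
  scale <- (sty - sum_t * sy / m) / denom
  offset <- (sy - scale * sum_t) / m
  sse <- sy2 + scale^2 * sum_t2 + m * offset^2 -
    2 * (scale * sty + offset * sy - scale * offset * sum_t)
  sse[sse < 0] <- 0
  se <- sqrt(sse / (m - 1))
  crit <- ifelse(se > 0, scale / se, 0)
  neg <- x$polarity == "negative"
  thr <- if (neg) -abs(criterion_threshold) else abs(criterion_threshold)
  exceeded <- if (neg) crit <= thr else crit >= thr
  ev <- runs_to_events(exceeded, if (neg) -crit else crit,
                       min_separation = m %/% 2L)
  structure(list(detection_trace = crit, event_indices = ev,
                 threshold_used = thr, method = "template_matching"),
            class = "detector_result")
}

#' Deconvolution-based detection
#'
#' Wiener-regularised frequency-domain division of the recording by the
#' template spectrum, low-pass filtered (Gaussian in the frequency domain),
#' yielding a detection trace with a sharp peak per event. The threshold is a
#' multiple of the detection trace's standard deviation (default 5).
#'
#' @param x a `mini_trace`.
#' @param template numeric template waveform.
#' @param threshold_sd_mult threshold in SDs of the detection trace.
#' @param reg_fraction Wiener regularisation as a fraction of the maximum
#'   template power (default 0.01).
#' @param lowpass_hz low-pass cutoff for the detection trace (default scales
#'   the 1 kHz @ 50 kHz convention with the sampling rate).
#' @return a `detector_result`; `event_indices` are peak positions of the
#'   detection trace (approximately the event onsets).
#' @export
deconvolution_detect <- function(x, template, threshold_sd_mult = 5,
                                 reg_fraction = 0.01,
                                 lowpass_hz = 1000 * x$sampling_rate / 50000) {
  stopifnot(inherits(x, "mini_trace"))
  if (all(template == 0)) stop("template must be non-zero")
  y <- x$samples
  n <- length(y)
  sgn <- if (x$polarity == "negative") -1 else 1
  H <- stats::fft(c(sgn * template, rep(0, n - length(template))))
  P <- Mod(H)^2
  lam <- reg_fraction * max(P)
  D <- stats::fft(y) * Conj(H) / (P + lam)
  # Gaussian low-pass in the frequency domain
  freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) *
    x$sampling_rate / n
  G <- exp(-0.5 * (freqs / lowpass_hz)^2)
  d <- Re(stats::fft(D * G, inverse = TRUE)) / n
  thr <- threshold_sd_mult * stats::sd(d)
  ev <- if (thr > 0) runs_to_events(d >= thr, d,
                                    min_separation = length(template) %/% 2L)
        else integer(0)
  structure(list(detection_trace = d, event_indices = ev,
                 threshold_used = thr, threshold_sd_mult = threshold_sd_mult,
                 method = "deconvolution"),
            class = "detector_result")
}

#' Finite-threshold detection
#'
#' Classic amplitude-threshold method: a running median baseline (default
#' 10 ms) is subtracted and events are reported wherever the residual crosses
#' the amplitude threshold for at least `min_duration_ms`, one event per
#' contiguous excursion.
#'
#' @param x a `mini_trace`.
#' @param amp_threshold amplitude threshold in signal units (default -4,
#'   i.e. -4 pA for inward currents; sign should match the polarity).
#' @param baseline_ms running-median window (default 10 ms).
#' @param min_duration_ms minimum excursion duration (default 0.5 ms).
#' @return a `detector_result`; `event_indices` mark the residual extremum of
#'   each excursion.
#' @export
finite_threshold_detect <- function(x, amp_threshold = -4, baseline_ms = 10,
                                    min_duration_ms = 0.5) {
  stopifnot(inherits(x, "mini_trace"))
  neg <- x$polarity == "negative"
  if (neg && amp_threshold > 0) amp_threshold <- -amp_threshold
  if (!neg && amp_threshold < 0) amp_threshold <- -amp_threshold
  y <- x$samples
  k <- round(baseline_ms / 1000 * x$sampling_rate)
  if (k %% 2 == 0) k <- k + 1
  base <- stats::runmed(y, k, endrule = "median")
  resid <- y - base
  min_dur <- max(1L, round(min_duration_ms / 1000 * x$sampling_rate))
  exceeded <- if (neg) resid <= amp_threshold else resid >= amp_threshold
  # enforce minimum excursion duration
  r <- rle(exceeded)
  r$values[r$values & r$lengths < min_dur] <- FALSE
  exceeded <- inverse.rle(r)
  ev <- runs_to_events(exceeded, if (neg) -resid else resid)
  structure(list(detection_trace = resid, event_indices = ev,
                 threshold_used = amp_threshold, method = "finite_threshold"),
            class = "detector_result")
}

#' @export
print.detector_result <- function(x, ...) {
  cat(sprintf("<detector_result> %s: %d events (threshold %.3g)\n",
              x$method, length(x$event_indices), x$threshold_used))
  invisible(x)
}
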