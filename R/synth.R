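#' Biexponential synaptic event waveform
#'
#' Samples the canonical miniature-event shape
#' \deqn{I(t) = (1 - e^{-t/\tau_{rise}})\, e^{-t/\tau_{decay}}}
#' on a regular grid. The analytic peak is at
#' \eqn{t^* = \tau_{rise} \log(1 + \tau_{decay}/\tau_{rise})}.
#'
#' @param tau_rise rise time constant, ms.
#' @param tau_decay decay time constant, ms.
#' @param dt sample interval, ms.
#' @param duration kernel duration, ms.
#' @param normalize if TRUE (default), scale so the sampled peak equals 1.
#' @return numeric waveform of length `floor(duration/dt) + 1`.
#' @export
biexp_kernel <- function(tau_rise, tau_decay, dt, duration, normalize = TRUE) {
  stopifnot(tau_rise > 0, tau_decay > 0, dt > 0, duration > 0)
  t_peak <- biexp_peak_time(tau_rise, tau_decay)
  if (duration < t_peak)
    warning(sprintf("kernel duration %.3g ms is shorter than the peak time %.3g ms",
                    duration, t_peak))
  tt <- seq(0, duration, by = dt)
  y <- (1 - exp(-tt / tau_rise)) * exp(-tt / tau_decay)
  if (normalize) y <- y / max(y)
  y
}

#' Analytic peak time of the biexponential waveform (ms)
#' @param tau_rise,tau_decay time constants in ms.
#' @return peak time in ms.
#' @export
biexp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * log(1 + tau_decay / tau_rise)
}

#' Signal-to-noise ratio in decibels
#'
#' SNR is the mean event amplitude divided by the standard deviation of the
#' baseline noise, expressed on the amplitude (not power) dB scale:
#' `20 * log10(ratio)`.
#'
#' @param mean_amplitude mean event amplitude (absolute value used).
#' @param noise_sd noise standard deviation (> 0).
#' @return SNR in dB.
#' @export
snr_db <- function(mean_amplitude, noise_sd) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  a <- abs(mean_amplitude)
  if (any(a <= 0)) stop("mean_amplitude must be non-zero")
  20 * log10(a / noise_sd)
}

#' Generate a synthetic noise trace
#'
#' White Gaussian noise, optionally shaped by a Gaussian low-pass FIR filter
#' to imitate the band-limited noise of a patch-clamp amplifier chain. The
#' filtered variant is variance-renormalised so the requested SD holds either
#' way.
#'
#' @param n number of samples.
#' @param sampling_rate sampling rate in Hz.
#' @param sd noise standard deviation in signal units (>= 0).
#' @param seed RNG seed.
#' @param model "white" or "filtered".
#' @param cutoff_hz -3 dB-ish cutoff for the filtered model (default 2900 Hz,
#'   a typical Bessel filter setting for mEPSC recordings).
#' @param units,polarity passed to [trace()].
#' @return a `mini_trace`.
#' @export
synth_noise <- function(n, sampling_rate, sd = 1, seed = 1,
                        model = c("white", "filtered"), cutoff_hz = 2900,
                        units = "pA", polarity = "negative") {
  model <- match.arg(model)
  stopifnot(sd >= 0, n >= 1)
  set.seed(seed)
  x <- stats::rnorm(n, 0, 1)
  if (model == "filtered") {
    x <- gaussian_lowpass(x, sampling_rate, cutoff_hz)
    x <- x / stats::sd(x)   # renormalise empirically
  }
  trace(x * sd, sampling_rate, units = units, polarity = polarity)
}

#' Specification of a synthetic miniature-event population
#'
#' Defaults describe fast glutamatergic mEPSCs: biexponential kinetics with
#' rise 0.2 ms and decay drawn per event from N(1.0, 0.25^2) ms (resampled if
#' non-positive), amplitudes from a log-normal law, mean event frequency
#' 0.7 Hz, and a 3 ms minimum spacing between onsets.
#'
#' The log-normal spread parameter is stated in the field both as a sigma and
#' as a variance; `lognormal_param` selects whether `amplitude_spread` is the
#' SD (default) or the variance of the underlying normal. `mean_amplitude`
#' fixes the location so that the distribution mean equals it, which pins the
#' SNR once a noise SD is chosen.
#'
#' @param tau_rise rise time constant, ms.
#' @param tau_decay_mean,tau_decay_sd per-event decay constant law, ms.
#' @param mean_amplitude mean event amplitude in signal units (positive
#'   number; the polarity gives the sign).
#' @param amplitude_spread log-normal spread parameter (see above).
#' @param lognormal_param "sd" or "variance" interpretation of
#'   `amplitude_spread`.
#' @param frequency mean event rate, Hz.
#' @param min_spacing minimum onset spacing, ms.
#' @param polarity "negative" or "positive".
#' @return an object of class `event_spec`.
#' @export
event_spec <- function(tau_rise = 0.2, tau_decay_mean = 1.0,
                       tau_decay_sd = 0.25, mean_amplitude = 10,
                       amplitude_spread = 0.4,
                       lognormal_param = c("sd", "variance"),
                       frequency = 0.7, min_spacing = 3,
                       polarity = c("negative", "positive")) {
  lognormal_param <- match.arg(lognormal_param)
  polarity <- match.arg(polarity)
  stopifnot(tau_rise > 0, tau_decay_mean > 0, tau_decay_sd >= 0,
            mean_amplitude >= 0, amplitude_spread >= 0, frequency > 0,
            min_spacing >= 0)
  structure(list(
    tau_rise = tau_rise, tau_decay_mean = tau_decay_mean,
    tau_decay_sd = tau_decay_sd, mean_amplitude = mean_amplitude,
    amplitude_spread = amplitude_spread, lognormal_param = lognormal_param,
    frequency = frequency, min_spacing = min_spacing, polarity = polarity),
    class = "event_spec")
}

# sdlog of the underlying normal, honouring the parameterisation switch
lognormal_sdlog <- function(spec) {
  if (spec$lognormal_param == "variance") sqrt(spec$amplitude_spread)
  else spec$amplitude_spread
}

# Draw n amplitudes whose distribution mean equals spec$mean_amplitude.
draw_amplitudes <- function(spec, n) {
  sdl <- lognormal_sdlog(spec)
  meanlog <- log(spec$mean_amplitude) - sdl^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdl)
}

#' Superimpose synthetic events on a noise trace
#'
#' The event count is Poisson with mean `frequency * duration`; onsets are
#' uniform over the trace subject to the minimum-spacing constraint
#' (rejection sampling). Each event gets its own log-normal amplitude and
#' normal decay constant, and the peak-normalised biexponential kernel scaled
#' by the amplitude is added (sign per polarity). Returns the trace and the
#' ground truth needed to score any detector against it.
#'
#' @param noise a `mini_trace` (typically from [synth_noise()]).
#' @param spec an [event_spec()].
#' @param seed RNG seed.
#' @return list with elements `trace` (a `mini_trace`) and `truth`
#'   (data.frame: onset_time_s, amplitude, tau_decay_ms), onsets sorted.
#' @export
place_events <- function(noise, spec, seed = 1) {
  stopifnot(inherits(noise, "mini_trace"), inherits(spec, "event_spec"))
  rate <- noise$sampling_rate
  n <- length(noise$samples)
  duration_s <- n / rate
  dt_ms <- 1000 / rate
  min_gap <- round(spec$min_spacing / dt_ms)          # samples
  kernel_ms <- spec$tau_rise * 8 + 10 * spec$tau_decay_mean
  margin <- round(kernel_ms / dt_ms)
  set.seed(seed)
  n_events <- stats::rpois(1, spec$frequency * duration_s)
  if (n_events * max(min_gap, 1) > 0.5 * n)
    stop("cannot satisfy the minimum-spacing constraint at this event density")
  onsets <- integer(0)
  attempts <- 0
  while (length(onsets) < n_events) {
    cand <- sample.int(max(1, n - margin), 1)
    if (!length(onsets) || all(abs(onsets - cand) >= min_gap)) {
      onsets <- c(onsets, cand)
    } else if ((attempts <- attempts + 1) > 1000 * n_events) {
      stop("cannot satisfy the minimum-spacing constraint at this event density")
    }
  }
  onsets <- sort(onsets)
  amps <- draw_amplitudes(spec, n_events)
  taus <- stats::rnorm(n_events, spec$tau_decay_mean, spec$tau_decay_sd)
  while (any(taus <= 0))
    taus[taus <= 0] <- stats::rnorm(sum(taus <= 0), spec$tau_decay_mean,
                                    spec$tau_decay_sd)
  sgn <- if (spec$polarity == "negative") -1 else 1
  y <- noise$samples
  if (n_events > 0 && spec$mean_amplitude > 0) {
    for (i in seq_len(n_events)) {
      k <- biexp_kernel(spec$tau_rise, taus[i], dt_ms,
                        duration = spec$tau_rise * 8 + 8 * taus[i])
      i0 <- onsets[i]
      i1 <- min(n, i0 + length(k) - 1)
      y[i0:i1] <- y[i0:i1] + sgn * amps[i] * k[seq_len(i1 - i0 + 1)]
    }
  }
  list(
    trace = trace(y, rate, units = noise$units, polarity = spec$polarity),
    truth = data.frame(onset_time_s = (onsets - 1) / rate,
                       amplitude = sgn * amps, tau_decay_ms = taus))
}

#' Build a labelled training set of classifier windows
#'
#' Positive windows contain exactly one synthetic event on noise, with the
#' onset jittered uniformly over a central range so the classifier learns a
#' localized response (sliding-window inference then produces a distinct peak
#' per event rather than a plateau). Negative windows are event-free noise;
#' with `augment = TRUE` a third of them instead carry one of two artifact
#' families seen in real recordings: rapid step-like transients (perfusion
#' pump glitches) and slow waves with symmetric rise and decay (the remaining
#' two thirds stay plain noise, roughly the composition of published training
#' sets, where recorded event-free segments outnumber simulated artifact
#' windows about two to one). Every window is min-max scaled to [0, 1].
#'
#' Windows follow the classifier's direction convention: events are presented
#' negative-going. For a positive-polarity spec the window is sign-flipped
#' before scaling, exactly as [predict_trace()] flips positive-polarity
#' traces at inference time. A single-polarity model thus serves both
#' recording modes, and transfer learning targets kinetics rather than sign.
#'
#' @param spec an [event_spec()]; `mean_amplitude` is in units of `noise_sd`.
#' @param n_pos,n_neg window counts per class.
#' @param noise_sd noise standard deviation.
#' @param augment include artifact negatives (default TRUE).
#' @param seed RNG seed.
#' @param window_len window length in samples (default 600).
#' @param sampling_rate sampling rate the windows represent, Hz.
#' @param jitter_range onset position range of positive events, as a fraction
#'   of the window (default c(1/6, 0.6)). The range width sets the width of
#'   the sliding-window confidence response, so it must comfortably exceed
#'   the benchmark's 10-stride minimum peak width: 0.43 x 600 samples = 13
#'   strides at stride 20.
#' @param noise_model "filtered" (band-limited, default) or "white"; see
#'   [synth_noise()].
#' @return an object of class `training_set`: list(windows, labels).
#' @export
make_training_set <- function(spec = event_spec(), n_pos = 2000, n_neg = 2000,
                              noise_sd = 1, augment = TRUE, seed = 1,
                              window_len = 600, sampling_rate = 50000,
                              jitter_range = c(1 / 6, 0.6),
                              noise_model = c("filtered", "white")) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  noise_model <- match.arg(noise_model)
  set.seed(seed)
  dt_ms <- 1000 / sampling_rate
  sgn <- if (spec$polarity == "negative") -1 else 1
  flip <- if (spec$polarity == "negative") 1 else -1   # direction convention
  jit <- round(window_len * jitter_range)
  n_tot <- n_pos + n_neg
  W <- matrix(0, n_tot, window_len)
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  mk_noise <- function() {
    x <- stats::rnorm(window_len, 0, 1)
    if (noise_model == "filtered") {
      x <- gaussian_lowpass(x, sampling_rate, 2900)
      x <- x / stats::sd(x)
    }
    x * noise_sd
  }
  for (i in seq_len(n_pos)) {
    w <- mk_noise()
    tau <- -1
    while (tau <= 0) tau <- stats::rnorm(1, spec$tau_decay_mean, spec$tau_decay_sd)
    amp <- draw_amplitudes(spec, 1)
    k <- biexp_kernel(spec$tau_rise, tau, dt_ms,
                      duration = spec$tau_rise * 8 + 8 * tau)
    pos <- sample(jit[1]:jit[2], 1)
    i1 <- min(window_len, pos + length(k) - 1)
    w[pos:i1] <- w[pos:i1] + sgn * amp * k[seq_len(i1 - pos + 1)]
    W[i, ] <- minmax_scale(flip * w)
  }
  for (i in seq_len(n_neg)) {
    w <- mk_noise()
    kind <- if (augment) i %% 6 else 0
    if (kind == 1) {       # rapid step-like transient, random sign
      pos <- sample.int(window_len - 20, 1)
      dur <- sample(2:15, 1)
      w[pos:(pos + dur)] <- w[pos:(pos + dur)] +
        sample(c(-1, 1), 1) * stats::runif(1, 2, 8) * noise_sd
    } else if (kind == 2) { # slow wave, symmetric rise and decay
      center <- sample.int(window_len, 1)
      sigma <- stats::runif(1, window_len / 12, window_len / 4)
      w <- w + sgn * stats::runif(1, 2, 8) * noise_sd *
        exp(-(seq_len(window_len) - center)^2 / (2 * sigma^2))
    }
    W[n_pos + i, ] <- minmax_scale(flip * w)
  }
  structure(list(windows = W, labels = labels), class = "training_set")
}

#' Mine hard negative windows from event-free noise
#'
#' Runs the classifier over freshly generated event-free noise and harvests
#' the (min-max scaled) windows whose score exceeds `threshold` — the noise
#' features this model mistakes for events. Retraining with these appended
#' as negatives sharpens the prediction trace, the same curation strategy
#' used for published training sets ("negative examples that are commonly
#' picked up as false positives").
#'
#' @param model a trained `event_classifier`.
#' @param n_target number of hard negatives wanted.
#' @param noise_sd,noise_model,cutoff_hz noise parameters (see
#'   [synth_noise()]).
#' @param sampling_rate Hz.
#' @param seed RNG seed.
#' @param threshold score above which a window counts as a hard negative.
#' @param stride scan stride in samples.
#' @param max_seconds give up after scanning this much noise.
#' @return matrix of scaled windows (possibly fewer than `n_target` rows).
#' @export
mine_hard_negatives <- function(model, n_target = 500, noise_sd = 1,
                                noise_model = "filtered", cutoff_hz = 2900,
                                sampling_rate = 50000, seed = 1,
                                threshold = 0.3, stride = 40L,
                                max_seconds = 60) {
  wl <- model$spec$window_len
  out <- matrix(numeric(0), 0, wl)
  chunk_s <- 4
  scanned <- 0
  while (nrow(out) < n_target && scanned < max_seconds) {
    noise <- synth_noise(round(chunk_s * sampling_rate), sampling_rate,
                         sd = noise_sd, seed = seed + scanned,
                         model = noise_model, cutoff_hz = cutoff_hz)
    pred <- predict_trace(model, noise, stride = stride)
    hit <- which(pred$scores >= threshold)
    # keep local maxima only, so one noise feature yields one window
    if (length(hit)) {
      hit <- hit[c(TRUE, diff(hit) > 3)]
      W <- t(vapply(pred$starts[hit], function(s)
        minmax_scale(noise$samples[s:(s + wl - 1L)]), numeric(wl)))
      out <- rbind(out, W)
    }
    scanned <- scanned + chunk_s
  }
  if (nrow(out) > n_target) out <- out[seq_len(n_target), , drop = FALSE]
  out
}

#' Append extra negative windows to a training set
#'
#' @param data a `training_set`.
#' @param windows matrix of scaled windows to add with label 0.
#' @return the augmented `training_set`.
#' @export
add_negatives <- function(data, windows) {
  stopifnot(ncol(windows) == ncol(data$windows))
  structure(list(windows = rbind(data$windows, windows),
                 labels = c(data$labels, rep(0L, nrow(windows)))),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d windows x %d samples, %.2f positive fraction\n",
              nrow(x$windows), ncol(x$windows), mean(x$labels)))
  invisible(x)
}
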