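#' Construct a recording trace
#'
#' A trace is a uniformly sampled single-channel signal: membrane current
#' (pA), membrane voltage (mV), or a fluorescence ratio (dF/F0), together
#' with its sampling rate and the expected polarity of synaptic events
#' (negative for inward currents under voltage clamp, positive for EPSPs or
#' optical transients).
#'
#' @param samples numeric vector of finite values.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param units unit label, e.g. "pA", "mV", "dF/F0".
#' @param polarity expected event polarity, "negative" or "positive".
#' @return an object of class `mini_trace`.
#' @export
trace <- function(samples, sampling_rate, units = "pA",
                  polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("trace samples must all be finite")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         units = units, polarity = polarity),
    class = "mini_trace")
}

#' @export
length.mini_trace <- function(x) length(x$samples)

#' @export
print.mini_trace <- function(x, ...) {
  cat(sprintf("<mini_trace> %d samples @ %g Hz (%.3f s), units %s, %s events\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$units, x$polarity))
  invisible(x)
}

#' Trace duration in seconds
#' @param x a `mini_trace`.
#' @return duration in seconds.
#' @export
trace_duration <- function(x) length(x$samples) / x$sampling_rate

#' Resample a trace by a rational factor
#'
#' Linear interpolation on the original time grid; with factor > 1 the
#' original sample values are preserved exactly at their time points when the
#' factor is an integer. Used e.g. to upsample slow optical recordings so
#' that events span enough samples for the 600-point classifier window.
#'
#' @param x a `mini_trace`.
#' @param factor resampling factor (> 0); 10 turns 100 Hz into 1000 Hz.
#' @return a `mini_trace` with sampling_rate multiplied by `factor`.
#' @export
resample_trace <- function(x, factor) {
  stopifnot(inherits(x, "mini_trace"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a single positive number")
  if (factor == 1) return(x)
  n <- length(x$samples)
  xout <- seq(0, n - 1, by = 1 / factor)
  yi <- stats::approx(seq_len(n) - 1, x$samples, xout = xout)$y
  trace(yi, x$sampling_rate * factor, units = x$units, polarity = x$polarity)
}
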