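`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max scale a numeric vector to [0, 1]
#'
#' Constant vectors map to all zeros, so inference on an event-free flat
#' window sees the same input regardless of its offset. This is also what
#' makes detection invariant to positive affine rescaling of the recording.
#'
#' @param x numeric vector.
#' @return vector of the same length in [0, 1].
#' @export
minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(numeric(length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Hann window
#'
#' @param n number of points (n >= 1).
#' @param normalize if TRUE, scale weights to sum to one (smoothing kernel).
#' @return numeric vector of length n.
#' @export
hann_window <- function(n, normalize = TRUE) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  if (normalize) w / sum(w) else w
}

# Centered moving-average style convolution with edge replication.
convolve_same <- function(x, w) {
  nw <- length(w)
  if (nw == 1) return(x * w)
  half_l <- (nw - 1) %/% 2
  half_r <- nw - 1 - half_l
  xp <- c(rep(x[1], half_l), x, rep(x[length(x)], half_r))
  out <- stats::filter(xp, rev(w), method = "convolution", sides = 2)
  out <- as.numeric(out)
  out[!is.na(out)][seq_along(x)]
}

#' Smooth a signal with a Hann window
#'
#' @param x numeric vector.
#' @param n window length in samples; n = 1 returns x unchanged.
#' @return smoothed vector, same length (edges replicated before convolution).
#' @export
hann_smooth <- function(x, n) {
  if (n <= 1) return(x)
  convolve_same(x, hann_window(n))
}

# Gaussian low-pass FIR (variance-renormalised by the caller if needed).
gaussian_lowpass <- function(x, sampling_rate, cutoff_hz) {
  sigma_s <- sampling_rate / (2 * pi * cutoff_hz)
  hw <- max(1L, ceiling(3 * sigma_s))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma_s)
  convolve_same(x, k / sum(k))
}

#' Running maximum filter
#'
#' @param x numeric vector.
#' @param width filter width in samples (centered).
#' @return vector of the same length; each point is the max of x over the
#'   centered window (edges use the available samples).
#' @export
max_filter <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  half_l <- (width - 1) %/% 2
  half_r <- width - 1 - half_l
  out <- x
  for (k in seq(-half_l, half_r)) {
    if (k == 0) next
    idx <- seq_len(n) + k
    idx[idx < 1] <- 1
    idx[idx > n] <- n
    out <- pmax(out, x[idx])
  }
  out
}

# Local maxima with prominence, on a plain numeric vector.
# A peak is a local maximum (plateaus take their first index).
# Prominence follows the usual topographic definition: height above the
# higher of the two lowest saddles separating the peak from higher terrain.
find_peaks <- function(x, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(data.frame(idx = integer(), height = numeric(),
                               prominence = numeric()))
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
               FALSE)
  # drop all but the first index of any flat plateau
  flat_prev <- c(FALSE, x[2:n] == x[1:(n - 1)])
  is_peak <- is_peak & !flat_prev
  idx <- which(is_peak & x >= min_height)
  prom <- vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i
    while (j > 1) {
      j <- j - 1
      if (x[j] > h) break
      lmin <- min(lmin, x[j])
    }
    if (j == 1 && x[j] <= h) lmin <- min(lmin, x[j])
    rmin <- h
    j <- i
    while (j < n) {
      j <- j + 1
      if (x[j] > h) break
      rmin <- min(rmin, x[j])
    }
    if (j == n && x[j] <= h) rmin <- min(rmin, x[j])
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(idx = idx, height = x[idx], prominence = prom)
}
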