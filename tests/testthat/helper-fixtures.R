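# Shared fixtures, built in code. Sizes are scaled down from full recordings
# (120 s at 50 kHz in typical experiments) to seconds-long traces with a
# raised event rate so the suite stays within its compute budget; kinetics,
# sampling rate, amplitude law, and minimum spacing keep their stated values.

FIX_RATE <- 50000

# A tiny architecture for tests that exercise mechanics, not accuracy.
tiny_spec <- function(window_len = 60L) {
  model_spec(window_len = window_len, filters = c(4L, 6L), kernels = c(5L, 3L),
             pools = c(3L, 0L), lstm_units = 8L, dense_units = 8L)
}

# Noiseless single-event trace with known kinetics.
noiseless_event_trace <- function(tau_rise = 0.2, tau_decay = 1.0,
                                  amplitude = 10, n = 3000, onset = 1000,
                                  rate = FIX_RATE, polarity = "negative") {
  dt_ms <- 1000 / rate
  k <- biexp_kernel(tau_rise, tau_decay, dt_ms, duration = tau_rise * 8 + 10 * tau_decay)
  y <- numeric(n)
  sgn <- if (polarity == "negative") -1 else 1
  i1 <- min(n, onset + length(k) - 1)
  y[onset:i1] <- sgn * amplitude * k[seq_len(i1 - onset + 1)]
  trace(y, rate, polarity = polarity)
}

# Synthetic benchmark trace: band-limited unit noise plus events at the given
# amplitude-to-noise ratio. Event rate is raised for short test traces.
bench_trace <- function(ratio = 5, duration_s = 4, frequency = 5, seed = 1,
                        tau_decay_mean = 1.0, rate = FIX_RATE) {
  noise <- synth_noise(round(duration_s * rate), rate, sd = 1,
                       seed = seed, model = "filtered")
  spec <- event_spec(mean_amplitude = ratio, frequency = frequency,
                     tau_decay_mean = tau_decay_mean)
  place_events(noise, spec, seed = seed + 1000L)
}
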