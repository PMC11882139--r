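# Synthetic event, noise, and ground-truth generation.

test_that("biexponential kernel matches its closed form", {
  dt <- 0.02
  k <- biexp_kernel(0.2, 1.0, dt, 8, normalize = FALSE)
  expect_equal(k[1], 0)                                   # I(0) = 0
  tt <- seq(0, 8, by = dt)
  expect_equal(k, (1 - exp(-tt / 0.2)) * exp(-tt / 1.0))
  # analytic argmax vs numeric maximisation oracle
  t_star <- biexp_peak_time(0.1, 1.0)
  opt <- optimize(function(t) (1 - exp(-t / 0.1)) * exp(-t / 1.0),
                  c(0, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(t_star, opt$maximum, tolerance = 1e-6)
  expect_equal(t_star, 0.2398, tolerance = 1e-3)
  # normalized kernel peaks at exactly 1 on the grid
  kn <- biexp_kernel(0.1, 1.0, dt, 8)
  expect_equal(max(kn), 1)
  expect_equal((which.max(kn) - 1) * dt, t_star, tolerance = dt)
  expect_warning(biexp_kernel(0.5, 5, 0.1, 0.5), "shorter than the peak")
})

test_that("snr_db follows the 20*log10 amplitude convention", {
  expect_equal(snr_db(1, 1), 0)
  expect_equal(snr_db(10, 1), 20)
  expect_equal(snr_db(2.82, 1), 20 * log10(2.82), tolerance = 1e-12)
  expect_equal(snr_db(2.82, 1), 9.0, tolerance = 0.05)
  expect_error(snr_db(1, 0), "positive")
  expect_error(snr_db(0, 1), "non-zero")
})

test_that("synthetic noise has the requested statistics and is reproducible", {
  z <- synth_noise(100, 1000, sd = 0, seed = 1)
  expect_true(all(z$samples == 0))
  for (model in c("white", "filtered")) {
    n1 <- synth_noise(1e6, 50000, sd = 1, seed = 7, model = model)
    expect_gt(sd(n1$samples), 0.995)
    expect_lt(sd(n1$samples), 1.005)
    n2 <- synth_noise(1e6, 50000, sd = 1, seed = 7, model = model)
    expect_identical(n1$samples, n2$samples)
  }
  # filtered noise is band-limited: lag-1 autocorrelation well above white
  nw <- synth_noise(1e5, 50000, sd = 1, seed = 3, model = "white")
  nf <- synth_noise(1e5, 50000, sd = 1, seed = 3, model = "filtered")
  expect_lt(abs(cor(nw$samples[-1], nw$samples[-1e5])), 0.05)
  expect_gt(cor(nf$samples[-1], nf$samples[-1e5]), 0.5)
})

test_that("event placement respects rate, spacing, and amplitude laws", {
  # mean event count ~= frequency * duration (0.7 Hz x 120 s = 84); run at a
  # low sampling rate so 100 replicate traces stay cheap
  rate <- 1000
  counts <- vapply(1:100, function(s) {
    noise <- synth_noise(120 * rate, rate, sd = 0, seed = s)
    sim <- place_events(noise, event_spec(frequency = 0.7), seed = s)
    nrow(sim$truth)
  }, numeric(1))
  expect_equal(mean(counts), 84, tolerance = 3 * sqrt(84 / 100) / 84)
  # minimum spacing holds pairwise, onsets sorted
  noise <- synth_noise(20 * FIX_RATE, FIX_RATE, sd = 1, seed = 2)
  sim <- place_events(noise, event_spec(frequency = 20), seed = 3)
  expect_false(is.unsorted(sim$truth$onset_time_s))
  expect_true(all(diff(sim$truth$onset_time_s) >= 0.003 - 1e-12))
  # zero-amplitude spec leaves the noise untouched
  sim0 <- place_events(noise, event_spec(mean_amplitude = 0), seed = 4)
  expect_identical(sim0$trace$samples, noise$samples)
  # amplitude law: mean equals the requested mean, median exp(-sdlog^2/2)
  # below it (log-normal), both within 3 SE at n = 1e4
  spec <- event_spec(mean_amplitude = 10, amplitude_spread = 0.4)
  set.seed(11)
  amps <- minidetect:::draw_amplitudes(spec, 1e4)
  se_mean <- sd(amps) / 100
  expect_equal(mean(amps), 10, tolerance = 3 * se_mean / 10)
  expect_equal(median(amps), 10 * exp(-0.4^2 / 2), tolerance = 0.02)
  # "variance" parameterisation uses sqrt(spread) as sdlog
  spec_v <- event_spec(mean_amplitude = 10, amplitude_spread = 0.16,
                       lognormal_param = "variance")
  set.seed(11)
  amps_v <- minidetect:::draw_amplitudes(spec_v, 1e4)
  expect_equal(median(amps_v), 10 * exp(-0.16 / 2), tolerance = 0.02)
})

test_that("impossible event density is rejected", {
  noise <- synth_noise(1000, 1000, sd = 0, seed = 1)    # 1 s at 1 kHz
  expect_error(place_events(noise, event_spec(frequency = 400, min_spacing = 100),
                            seed = 1), "spacing")
})

test_that("training-set construction scales, labels, and augments correctly", {
  ts <- make_training_set(event_spec(mean_amplitude = 5), n_pos = 60, n_neg = 60,
                          seed = 5, window_len = 300)
  expect_equal(dim(ts$windows), c(120, 300))
  expect_equal(mean(ts$labels), 0.5)
  expect_true(all(ts$windows >= 0 & ts$windows <= 1))
  expect_true(all(apply(ts$windows, 1, min) == 0))
  expect_true(all(apply(ts$windows, 1, max) == 1))
  # with augmentation off, negatives carry no event-locked deterministic
  # component: projections onto the kernel are zero-mean
  ts2 <- make_training_set(event_spec(mean_amplitude = 5), n_pos = 0,
                           n_neg = 400, augment = FALSE, seed = 6,
                           window_len = 300, noise_model = "white")
  k <- biexp_kernel(0.2, 1.0, 1000 / FIX_RATE, duration = 4)
  k <- c(k, numeric(300 - length(k)))
  k <- (k - mean(k)) / sqrt(sum((k - mean(k))^2))
  proj <- as.numeric(ts2$windows %*% k)
  expect_lt(abs(mean(proj)) / (sd(proj) / sqrt(length(proj))), 4)
})

test_that("positive-polarity windows follow the direction convention", {
  # events are presented negative-going regardless of the spec's polarity:
  # at high amplitude the scaled window's minimum sits in the event trough,
  # inside the jitter range plus the peak latency
  for (pol in c("negative", "positive")) {
    ts <- make_training_set(event_spec(mean_amplitude = 25, polarity = pol),
                            n_pos = 30, n_neg = 0, seed = 9, window_len = 300)
    troughs <- apply(ts$windows, 1, which.min)
    expect_true(all(troughs >= 50 & troughs <= 205), info = pol)
  }
})
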