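# Matched-filter baseline detectors.

test_that("template-matching criterion equals a per-offset least-squares oracle", {
  set.seed(3)
  y <- rnorm(60)
  tpl <- event_template(0.2, 1.0, sampling_rate = 5000)  # short template
  x <- trace(y, 5000)
  r <- template_matching_detect(x, tpl, criterion_threshold = -4)
  m <- length(tpl)
  # oracle: explicit linear fit y ~ scale*tpl + offset at every offset
  crit_oracle <- vapply(seq_len(length(y) - m + 1), function(o) {
    seg <- y[o:(o + m - 1)]
    fit <- lm(seg ~ tpl)
    s <- coef(fit)[["tpl"]]
    sse <- sum(residuals(fit)^2)
    s / sqrt(sse / (m - 1))
  }, numeric(1))
  expect_equal(r$detection_trace, crit_oracle, tolerance = 1e-8)
})

test_that("template matching finds noiseless template occurrences", {
  rate <- FIX_RATE
  tpl <- event_template(0.2, 1.0, sampling_rate = rate)
  y <- numeric(20000)
  pos <- c(2000, 8000, 15000)
  for (p in pos) y[p:(p + length(tpl) - 1)] <- y[p:(p + length(tpl) - 1)] - 8 * tpl
  x <- trace(y, rate)
  r <- template_matching_detect(x, tpl, criterion_threshold = -4)
  sc <- score_detection((r$event_indices - 1) / rate, (pos - 1) / rate,
                        tolerance_s = 0.002)
  expect_equal(sc$recall, 1)
  expect_equal(sc$FP, 0)
  # criterion at occurrences dwarfs noise-only offsets
  noise <- synth_noise(20000, rate, sd = 1, seed = 4, model = "filtered")
  xn <- trace(noise$samples + y, rate)
  rn <- template_matching_detect(xn, tpl)
  at_events <- vapply(pos, function(p) min(rn$detection_trace[p + (-5:5)]), numeric(1))
  away <- rn$detection_trace[seq(1, 1500)]
  expect_lt(max(at_events), min(away))
  # pure noise with an extreme threshold: nothing detected
  rp <- template_matching_detect(trace(noise$samples, rate), tpl,
                                 criterion_threshold = -1e6)
  expect_length(rp$event_indices, 0)
})

test_that("deconvolution recovers shift positions and is linear", {
  rate <- FIX_RATE
  tpl <- event_template(0.2, 1.0, sampling_rate = rate)
  y <- numeric(30000)
  pos <- c(5000, 12000, 22000)
  for (p in pos) y[p:(p + length(tpl) - 1)] <- y[p:(p + length(tpl) - 1)] - 6 * tpl
  x <- trace(y, rate)
  r <- deconvolution_detect(x, tpl, threshold_sd_mult = 5)
  expect_equal(length(r$event_indices), 3)
  # the low-pass smears the peak slightly; recovery within ~0.5 ms
  expect_true(all(abs(r$event_indices - pos) <= 25))
  # linearity of the deconvolution operator
  x2 <- trace(3 * y, rate)
  r2 <- deconvolution_detect(x2, tpl, threshold_sd_mult = 5)
  expect_equal(r2$detection_trace, 3 * r$detection_trace, tolerance = 1e-8)
  # all-zero input: no detections; all-zero template: error
  r0 <- deconvolution_detect(trace(numeric(5000), rate), tpl)
  expect_length(r0$event_indices, 0)
  expect_error(deconvolution_detect(x, numeric(10)), "non-zero")
})

test_that("finite-threshold detection honours threshold and duration", {
  rate <- FIX_RATE
  mk <- function(amp) {
    y <- numeric(30000)
    for (p in c(5000, 15000, 25000)) {
      k <- biexp_kernel(0.2, 1.0, 1000 / rate, 8)
      y[p:(p + length(k) - 1)] <- y[p:(p + length(k) - 1)] - amp * k
    }
    trace(y, rate)
  }
  r10 <- finite_threshold_detect(mk(10), amp_threshold = -4)
  expect_equal(length(r10$event_indices), 3)
  r2 <- finite_threshold_detect(mk(2), amp_threshold = -4)
  expect_length(r2$event_indices, 0)
  # detections non-increasing as |threshold| grows
  noise <- synth_noise(30000, rate, sd = 1, seed = 6, model = "filtered")
  x <- trace(mk(8)$samples + noise$samples, rate)
  counts <- vapply(c(1, 2, 3, 4, 6, 8), function(th)
    length(finite_threshold_detect(x, amp_threshold = -th)$event_indices),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold sweep: fraction 100 reproduces the default exactly", {
  rate <- FIX_RATE
  sim <- bench_trace(ratio = 6, duration_s = 1.2, frequency = 5, seed = 8)
  tpl <- event_template(0.2, 1.0, sampling_rate = rate)
  det <- template_detector(tpl)
  sw <- threshold_sweep(det, sim$trace, sim$truth, fractions = c(50, 100, 150))
  expect_equal(sw$n_detected[sw$fraction_pct == 100],
               length(det$detect(sim$trace, det$default_threshold)))
  # template-matching counts decrease monotonically with |threshold|
  sw2 <- threshold_sweep(det, sim$trace, fractions = seq(25, 195, by = 34))
  expect_true(all(diff(sw2$n_detected) <= 0))
})
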