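# Sliding-window segmentation, prediction traces, and event localisation.

test_that("window counting and scaling contracts hold", {
  x <- synth_noise(1200, FIX_RATE, sd = 1, seed = 1)
  W <- window_trace(x, window_len = 600, stride = 20)
  expect_equal(nrow(W), 31)                       # floor((1200-600)/20)+1
  expect_equal(attr(W, "starts")[1:3], c(1, 21, 41))
  expect_error(window_trace(synth_noise(100, 1000, sd = 1, seed = 1),
                            window_len = 600), "shorter")
  # toy scaling
  expect_equal(minmax_scale(c(0, 1, 2)), c(0, 0.5, 1))
  expect_equal(minmax_scale(rep(3, 5)), rep(0, 5))
  # positive affine transform leaves scaled windows unchanged (to rounding;
  # the detection-level invariance is asserted exactly in the acceptance suite)
  x2 <- trace(2.5 * x$samples + 17, x$sampling_rate)
  expect_equal(window_trace(x2, 600, 20), window_trace(x, 600, 20),
               tolerance = 1e-12)
})

test_that("prediction traces resample to trace length and stay in [0,1]", {
  m <- build_classifier(tiny_spec(), seed = 2)
  x <- synth_noise(1000, 10000, sd = 1, seed = 3)
  pr <- predict_trace(m, x, stride = 10)
  expect_length(pr$values, 1000)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  expect_equal(length(pr$scores), floor((1000 - 60) / 10) + 1)
  # constant trace: every window scales to zeros -> constant prediction
  xc <- trace(rep(5, 500), 10000)
  prc <- predict_trace(m, xc, stride = 10)
  expect_equal(length(unique(prc$scores)), 1)
  expect_equal(prc$scores[1], predict(m, matrix(0, 1, 60))[1])
})

test_that("locate_events applies threshold, width, and max filter", {
  x <- synth_noise(5000, FIX_RATE, sd = 1, seed = 4)
  mk_pred <- function(scores, stride = 20L, wl = 600L) {
    structure(list(values = rep(scores, each = stride)[seq_len(5000)],
                   scores = scores,
                   starts = seq(1L, 5000L - wl + 1L, by = stride),
                   stride = stride, window_len = wl, n = 5000L),
              class = "prediction_trace")
  }
  n_sc <- floor((5000 - 600) / 20) + 1
  # flat low prediction: nothing
  ev0 <- locate_events(mk_pred(rep(0.2, n_sc)), x)
  expect_equal(nrow(ev0), 0)
  # one rectangular bump of height 0.9, 20 strides wide: exactly one event
  sc <- rep(0.1, n_sc); sc[100:119] <- 0.9
  ev1 <- locate_events(mk_pred(sc), x, min_height = 0.5, min_width = 5)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$peak_confidence, 0.9)
  # a bump narrower than min_width (after the max filter) is rejected
  sc2 <- rep(0.1, n_sc); sc2[100] <- 0.9
  ev2 <- locate_events(mk_pred(sc2), x, min_height = 0.5, min_width = 10,
                       maxfilt_width = 5)
  expect_equal(nrow(ev2), 0)
  expect_error(locate_events(mk_pred(sc), x, min_height = 1.2), "min_height")
})

test_that("max filter matches a naive oracle", {
  set.seed(8)
  v <- rnorm(200)
  for (w in c(3, 5, 8)) {
    got <- max_filter(v, w)
    want <- vapply(seq_along(v), function(i) {
      lo <- max(1, i - (w - 1) %/% 2); hi <- min(200, i + w - 1 - (w - 1) %/% 2)
      max(v[lo:hi])
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("trace resampling preserves shape", {
  x <- trace(seq(0, 10, length.out = 101), 100)    # linear ramp at 100 Hz
  expect_identical(resample_trace(x, 1), x)
  y <- resample_trace(x, 10)
  expect_equal(y$sampling_rate, 1000)
  expect_equal(length(y$samples), 1001)
  # a linear ramp stays exactly linear under linear interpolation
  expect_equal(max(abs(diff(y$samples) - diff(y$samples)[1])), 0,
               tolerance = 1e-12)
  expect_equal(y$samples[seq(1, 1001, by = 10)], x$samples)
  expect_error(resample_trace(x, -1), "positive")
})

test_that("steepest-rise indices land on the event rise", {
  x <- noiseless_event_trace(0.2, 1.0, amplitude = 10, onset = 2000, n = 5000)
  stride <- 20L
  n_sc <- floor((5000 - 600) / 20) + 1
  sc <- rep(0.05, n_sc)
  sc[75:95] <- 0.95   # run covering the event onset at sample 2000
  pred <- structure(list(values = rep(sc, each = stride)[seq_len(5000)],
                         scores = sc,
                         starts = seq(1L, 5000L - 600L + 1L, by = stride),
                         stride = stride, window_len = 600L, n = 5000L),
                    class = "prediction_trace")
  ev <- locate_events(pred, x, min_height = 0.5, min_width = 5)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$steepest_rise_idx - 2000), 15)   # within the rise phase
  # within one model window of the prediction-trace run
  expect_lt(ev$steepest_rise_idx - ev$threshold_crossing_idx, 600)
})
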