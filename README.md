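# minidetect

Detection and quantification of miniature synaptic events (mEPSCs, mEPSPs,
optical dF/F0 transients) in single-channel time series, using a supervised
CNN-LSTM window classifier with a sliding-window inference pipeline —
together with the classical matched-filter detectors (template matching,
Wiener deconvolution, finite threshold) and a synthetic ground-truth
benchmark that scores any of them with precision/recall/F1.

The neural network (forward pass, backpropagation, Adam with AMSGrad) is
implemented natively in C++ via RcppArmadillo; no Python or deep-learning
framework is required.

## The method in brief

A classifier `f : R^600 -> [0,1]` scores min-max-scaled 600-sample windows
for the presence of an event. The architecture is four convolutional blocks
(Conv1D -> batch norm -> leaky ReLU, average pooling after the first three;
sequence lengths 600 -> 200 -> 100 -> 50, channels 1 -> 32 -> 48 -> 64 -> 80),
a bidirectional LSTM (96 units, sum merge), a dense layer (128, leaky ReLU)
with dropout, and a sigmoid unit — 191,361 parameters, 190,913 trainable.

For detection, the window slides along the recording with a stride (default
20 samples); the scores form a *prediction trace*, which is maximum-filtered
and thresholded (default 0.5); score runs of sufficient width become events,
each localized at its steepest rise in the raw data. Detected events are
aligned, overlapping events are split by relative derivative prominence
(>= 0.25), and amplitude, 10-90% rise time, half-decay time, and charge are
measured on Hann-smoothed data.

The benchmark generator superimposes biexponential events
`I(t) = (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` with log-normal
amplitudes and normally distributed decay constants on (optionally
band-limited) Gaussian noise, and reports TP/FP/FN-based metrics against
the known event times.

## Worked example

```r
library(minidetect)

# 1. a classifier trained on ~4,000 synthetic windows (about 10 min on 1 CPU)
model <- train_benchmark_classifier(seed = 7)

# 2. a 6 s synthetic voltage-clamp recording at 50 kHz, SNR 12 dB
noise <- synth_noise(6 * 50000, 50000, sd = 1, seed = 310, model = "filtered")
sim   <- place_events(noise, event_spec(mean_amplitude = 4, frequency = 2.5),
                      seed = 311)

# 3. detect and quantify
ev    <- detect_events(model, sim$trace, stride = 20, min_height = 0.5,
                       min_width = 10)
stats <- quantify_events(sim$trace, ev)
summarize_recording(stats, trace_duration(sim$trace))

# 4. score against ground truth
score_detection(ev$time_s, sim$truth)
```

On this example the package prints (seed-exact under one BLAS thread):

```
  n_events frequency_hz duration_s mean_amplitude median_amplitude
1       17     2.833333          6      -4.783009        -4.443232
  mean_rise_10_90_ms median_rise_10_90_ms mean_half_decay_ms
1          0.3771985            0.2623852          0.5553469
  median_half_decay_ms mean_charge median_charge
1            0.4933326   -6.005367     -3.849092

  TP FP FN precision    recall        f1
1 15  2  2 0.8823529 0.8823529 0.8823529
```

Seventeen true events with mean amplitude 4x the noise SD; fifteen are
recovered within 2 ms, with two false positives and two misses — typical
desk-scale performance at this SNR (see the vignette for what limits it).
The half-decay median (~0.49 ms on Hann-smoothed data) reflects the 1 ms
decay-constant population; amplitudes are in the trace's units (pA).

Classical detectors share the same interface:

```r
tpl <- event_template(tau_rise = 0.2, tau_decay = 1.0, sampling_rate = 50000)
r   <- template_matching_detect(sim$trace, tpl, criterion_threshold = -4)
score_detection((r$event_indices - 1) / 50000, sim$truth)
```

## Command line

```sh
Rscript inst/scripts/minidetect simulate --duration 10 --rate 50000 \
    --snr-db 12 --seed 1 --out trace.txt
Rscript inst/scripts/minidetect detect --input trace.txt --model model.rds \
    --stride 20 --threshold 0.5 --out events.csv
```

`simulate` output feeds `detect` and `benchmark` unchanged; `train` and
`transfer` build and adapt models from window/label CSVs.

## Documentation

The methods vignette (`vignettes/minidetect-methods.Rmd`) describes the
model, the training adaptations for compact synthetic sets (learning-rate
scaling, batch-norm re-estimation, hard-negative mining), the direction
normalisation convention, the synthetic world and its limits, and all
numerical defaults.
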