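Package: minidetect
Title: Deep-Learning Detection and Quantification of Miniature Synaptic Events
Version: 0.1.0
Authors@R: person("miniature-events", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Supervised detection of miniature synaptic events (mEPSCs, mEPSPs,
    optical dF/F0 transients) in single-channel time series. Implements a
    CNN-LSTM window classifier trained with Adam/AMSGrad (including a
    transfer-learning path with frozen convolutional blocks), sliding-window
    inference with stride and prediction-trace post-processing, steepest-rise
    event alignment with overlap splitting, amplitude and kinetics
    quantification, a synthetic ground-truth benchmark generator with
    biexponential events and log-normal amplitudes, precision/recall/F1
    scoring, and matched-filter baseline detectors (template matching,
    Wiener deconvolution, finite threshold). The neural network is implemented
    natively (RcppArmadillo); no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
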