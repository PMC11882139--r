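#' CNN-LSTM classifier architecture specification
#'
#' Defaults reproduce the published event-classifier architecture: four
#' convolutional blocks (Conv1D 'same' padding -> batch norm -> leaky ReLU,
#' the first three followed by average pooling), a bidirectional LSTM with
#' sum merge, a dense layer with leaky ReLU, dropout, and a single sigmoid
#' output unit. Sequence lengths run 600 -> 200 -> 100 -> 50.
#'
#' The fourth conv block uses kernel size 3: with 64 input channels and 80
#' filters this gives 80*(64*3)+80 = 15,440 weights, the only kernel size
#' consistent with the block's published parameter count and the published
#' trainable total of 190,913.
#'
#' @param window_len input window length in samples (default 600); must be
#'   divisible by the pooling chain.
#' @param filters,kernels,pools integer vectors, one entry per conv block;
#'   `pools[i] = 0` means no pooling after block i. Kernels must be odd.
#' @param leaky_alpha negative slope of the leaky ReLU (default 0.3).
#' @param lstm_units LSTM units per direction (default 96).
#' @param lstm_dropout input dropout of the LSTM during training (default 0.2).
#' @param dense_units dense layer width (default 128).
#' @param dense_dropout dropout after the dense layer (default 0.2).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(window_len = 600,
                       filters = c(32L, 48L, 64L, 80L),
                       kernels = c(9L, 7L, 5L, 3L),
                       pools = c(3L, 2L, 2L, 0L),
                       leaky_alpha = 0.3,
                       lstm_units = 96L, lstm_dropout = 0.2,
                       dense_units = 128L, dense_dropout = 0.2) {
  stopifnot(length(filters) == length(kernels),
            length(filters) == length(pools),
            all(kernels %% 2 == 1), window_len >= 1,
            lstm_units >= 1, dense_units >= 1,
            lstm_dropout >= 0, lstm_dropout < 1,
            dense_dropout >= 0, dense_dropout < 1)
  len <- window_len
  for (i in seq_along(pools)) {
    if (pools[i] > 0) {
      if (len %% pools[i] != 0)
        stop(sprintf(
          "window_len %d is not compatible with the pooling chain (length %d not divisible by %d at block %d)",
          window_len, len, pools[i], i))
      len <- len %/% pools[i]
    }
  }
  structure(list(
    window_len = as.integer(window_len), filters = as.integer(filters),
    kernels = as.integer(kernels), pools = as.integer(pools),
    leaky_alpha = leaky_alpha, lstm_units = as.integer(lstm_units),
    lstm_dropout = lstm_dropout, dense_units = as.integer(dense_units),
    dense_dropout = dense_dropout, lstm_seq_len = as.integer(len)),
    class = "model_spec")
}

#' Training configuration
#'
#' Defaults are the published settings: Adam with the AMSGrad variant,
#' learning rate 2e-5, batch size 128, at most 100 epochs, early stopping
#' after 8 epochs without validation-loss improvement, and a 0.75/0.25
#' train/validation split of the labelled windows.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param split_fraction fraction of windows used for training (rest
#'   validates); must be in (0, 1).
#' @param monitor "val_loss" (default, matches the early-stopping signal) or
#'   "val_accuracy" for best-checkpoint selection.
#' @param seed RNG seed for the split, shuffling, and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-5, batch_size = 128L,
                         max_epochs = 100L, early_stop_patience = 8L,
                         split_fraction = 0.75,
                         monitor = c("val_loss", "val_accuracy"),
                         seed = 42L) {
  monitor <- match.arg(monitor)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            split_fraction > 0, split_fraction < 1,
            early_stop_patience >= 1, early_stop_patience < max_epochs)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 split_fraction = split_fraction, monitor = monitor,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Transfer-learning configuration
#'
#' Published settings for adapting a trained classifier to new event shapes:
#' learning rate 2e-8, patience 15, batch size 32, dropout 0.5, with the four
#' convolutional blocks (including their batch-norm layers and moving
#' statistics) frozen.
#'
#' @param learning_rate Adam learning rate.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param batch_size minibatch size.
#' @param dropout_rate dropout applied after the dense layer during TL.
#' @param freeze_conv freeze all convolutional-block parameters (default
#'   TRUE).
#' @param max_epochs maximum epochs (default 100, as for full training).
#' @param split_fraction train fraction of the supplied windows.
#' @param seed RNG seed.
#' @return object of class `tl_config`.
#' @export
tl_config <- function(learning_rate = 2e-8, early_stop_patience = 15L,
                      batch_size = 32L, dropout_rate = 0.5,
                      freeze_conv = TRUE, max_epochs = 100L,
                      split_fraction = 0.75, seed = 42L) {
  stopifnot(learning_rate > 0, batch_size >= 1,
            early_stop_patience >= 1, early_stop_patience < max_epochs,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, freeze_conv = freeze_conv,
                 max_epochs = as.integer(max_epochs),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "tl_config")
}

spec_for_cpp <- function(spec) {
  list(window_len = spec$window_len, filters = spec$filters,
       kernels = spec$kernels, pools = spec$pools,
       leaky_alpha = spec$leaky_alpha, lstm_units = spec$lstm_units,
       lstm_dropout = spec$lstm_dropout, dense_units = spec$dense_units,
       dense_dropout = spec$dense_dropout)
}

#' Build an (untrained) event classifier
#'
#' Initialises every weight tensor with Glorot-uniform draws from a seeded
#' generator (LSTM forget-gate biases start at 1), so two builds with the
#' same seed are bit-identical.
#'
#' @param spec a [model_spec()].
#' @param seed integer initialisation seed.
#' @return object of class `event_classifier`.
#' @export
build_classifier <- function(spec = model_spec(), seed = 42L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- .nn_init(spec_for_cpp(spec), as.integer(seed))
  structure(list(spec = spec, params = params, history = NULL,
                 config = NULL, seed = as.integer(seed), frozen = FALSE,
                 trained = FALSE),
            class = "event_classifier")
}

#' @export
print.event_classifier <- function(x, ...) {
  cat(sprintf(
    "<event_classifier> window %d, %s%s; %s params (%s trainable)\n",
    x$spec$window_len,
    if (x$trained) "trained" else "untrained",
    if (x$frozen) ", conv blocks frozen" else "",
    format(count_parameters(x, trainable_only = FALSE), big.mark = ","),
    format(count_parameters(x, trainable_only = TRUE), big.mark = ",")))
  invisible(x)
}

#' Per-layer parameter counts
#'
#' One row per parameterised layer, in network order; batch-norm rows count
#' all four tensors per channel (scale, offset, moving mean, moving
#' variance), of which the moving statistics are non-trainable.
#'
#' @param model an `event_classifier`.
#' @return data.frame with columns layer, parameters, trainable.
#' @export
layer_parameters <- function(model) {
  p <- model$params
  sz <- vapply(p, length, integer(1))
  nb <- length(model$spec$filters)
  rows <- list()
  for (i in seq_len(nb)) {
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("conv%d", i),
      parameters = sz[[sprintf("conv%d_W", i)]] + sz[[sprintf("conv%d_b", i)]],
      trainable = sz[[sprintf("conv%d_W", i)]] + sz[[sprintf("conv%d_b", i)]])
    bn_all <- sum(sz[sprintf("bn%d_%s", i, c("gamma", "beta", "rmean", "rvar"))])
    bn_tr <- sum(sz[sprintf("bn%d_%s", i, c("gamma", "beta"))])
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("batchnorm%d", i), parameters = bn_all, trainable = bn_tr)
  }
  lstm <- sum(sz[c("lstm_fw_Wx", "lstm_fw_Wh", "lstm_fw_b",
                   "lstm_bw_Wx", "lstm_bw_Wh", "lstm_bw_b")])
  rows[[length(rows) + 1]] <- data.frame(layer = "bilstm", parameters = lstm,
                                         trainable = lstm)
  d1 <- sum(sz[c("dense1_W", "dense1_b")])
  d2 <- sum(sz[c("dense2_W", "dense2_b")])
  rows[[length(rows) + 1]] <- data.frame(layer = "dense1", parameters = d1,
                                         trainable = d1)
  rows[[length(rows) + 1]] <- data.frame(layer = "dense2", parameters = d2,
                                         trainable = d2)
  do.call(rbind, rows)
}

#' Count model parameters
#'
#' @param model an `event_classifier`.
#' @param trainable_only if TRUE, exclude batch-norm moving statistics and,
#'   when the convolutional blocks are frozen (`freeze_conv`), all
#'   convolutional-block tensors.
#' @param freeze_conv treat conv blocks as frozen; defaults to the model's
#'   own frozen flag (set by [apply_transfer_learning()]).
#' @return integer parameter count.
#' @export
count_parameters <- function(model, trainable_only = FALSE,
                             freeze_conv = model$frozen) {
  sz <- vapply(model$params, function(t) length(t), integer(1))
  if (!trainable_only) return(sum(sz))
  keep <- rep(TRUE, length(sz))
  nms <- names(model$params)
  keep[grepl("_(rmean|rvar)$", nms)] <- FALSE
  if (isTRUE(freeze_conv)) keep[grepl("^(conv|bn)", nms)] <- FALSE
  sum(sz[keep])
}

check_training_set <- function(data) {
  stopifnot(inherits(data, "training_set") ||
            (is.list(data) && !is.null(data$windows) && !is.null(data$labels)))
  if (!nrow(data$windows)) stop("training set is empty")
  if (length(unique(data$labels)) < 2)
    stop("training requires both classes to be present")
  if (!all(data$labels %in% c(0, 1))) stop("labels must be 0/1")
  rng <- range(data$windows)
  if (rng[1] < 0 || rng[2] > 1)
    stop("windows must be min-max scaled to [0, 1]")
  invisible(data)
}

split_training_set <- function(data, split_fraction, seed) {
  n <- nrow(data$windows)
  set.seed(seed)
  idx <- sample.int(n)
  n_tr <- max(1L, min(n - 1L, floor(split_fraction * n)))
  list(train_idx = idx[seq_len(n_tr)], val_idx = idx[(n_tr + 1):n])
}

#' Train the classifier
#'
#' Splits the windows into train/validation sets, minimises binary
#' cross-entropy with Adam/AMSGrad, applies early stopping on the validation
#' loss, and restores the best checkpoint (lowest validation loss by default;
#' see `monitor` in [train_config()]). Training is bit-reproducible under a
#' fixed seed and single-threaded BLAS.
#'
#' @param model an `event_classifier` (from [build_classifier()] or a
#'   previous training run).
#' @param data a `training_set` (scaled windows + 0/1 labels, both classes
#'   present).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch metrics.
#' @return the trained `event_classifier`, with `$history` (one row per
#'   epoch: loss, accuracy, val_loss, val_accuracy) and `$config` filled in.
#' @export
train_classifier <- function(model, data, cfg = train_config(),
                             verbose = FALSE) {
  stopifnot(inherits(model, "event_classifier"), inherits(cfg, "train_config"))
  check_training_set(data)
  if (ncol(data$windows) != model$spec$window_len)
    stop(sprintf("windows have %d samples but the model expects %d; resample them first",
                 ncol(data$windows), model$spec$window_len))
  sp <- split_training_set(data, cfg$split_fraction, cfg$seed)
  fit <- .nn_train(model$params, spec_for_cpp(model$spec),
                   data$windows[sp$train_idx, , drop = FALSE],
                   as.numeric(data$labels[sp$train_idx]),
                   data$windows[sp$val_idx, , drop = FALSE],
                   as.numeric(data$labels[sp$val_idx]),
                   cfg$learning_rate, cfg$batch_size, cfg$max_epochs,
                   cfg$early_stop_patience, cfg$seed, FALSE, cfg$monitor,
                   verbose)
  model$params <- fit$params
  model$history <- fit$history
  model$config <- cfg
  model$trained <- TRUE
  model$best_epoch <- fit$best_epoch
  model
}

#' Classifier scores for a batch of windows
#'
#' @param object an `event_classifier`.
#' @param newdata numeric matrix (n x window_len) of min-max scaled windows,
#'   or a single window as a vector.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return numeric vector of scores in [0, 1].
#' @export
predict.event_classifier <- function(object, newdata, batch_size = 512L, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  as.numeric(.nn_predict(object$params, spec_for_cpp(object$spec), newdata,
                         as.integer(batch_size)))
}

#' Evaluate a trained classifier
#'
#' Accuracy at the 0.5 cutoff plus the full ROC curve and its area, computed
#' over all score thresholds (rank statistic, ties handled by midranks).
#'
#' @param model an `event_classifier`.
#' @param data a `training_set`-like list with `windows` and `labels`.
#' @return list with `accuracy`, `auc`, and `roc_points` (data.frame fpr/tpr).
#' @export
evaluate_classifier <- function(model, data) {
  scores <- predict(model, data$windows)
  labels <- data$labels
  if (length(unique(labels)) < 2)
    stop("AUC is undefined for a single-class evaluation set")
  list(accuracy = mean((scores >= 0.5) == (labels == 1)),
       auc = roc_auc(scores, labels),
       roc_points = roc_points(scores, labels))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("AUC needs both classes")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

roc_points <- function(scores, labels) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  tpr <- vapply(ths, function(t) sum(scores >= t & labels == 1) / np, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & labels == 0) / nn, numeric(1))
  data.frame(threshold = ths, fpr = fpr, tpr = tpr)
}

#' Adapt a trained classifier to new event shapes (transfer learning)
#'
#' Freezes the four convolutional blocks (weights, batch-norm scale/offset
#' and moving statistics) and retrains only the LSTM and dense layers on a
#' small labelled set, using the TL hyperparameters. Inputs must already be
#' `window_len` samples long; resample them first otherwise.
#'
#' @param base a trained `event_classifier`.
#' @param data a `training_set` of windows with the new event shape.
#' @param cfg a [tl_config()].
#' @param verbose print per-epoch metrics.
#' @return the adapted `event_classifier` with `$frozen = TRUE`.
#' @export
apply_transfer_learning <- function(base, data, cfg = tl_config(),
                                    verbose = FALSE) {
  stopifnot(inherits(base, "event_classifier"), inherits(cfg, "tl_config"))
  check_training_set(data)
  if (ncol(data$windows) != base$spec$window_len)
    stop(sprintf(
      "windows have %d samples but the model expects %d; resample them to %d points first (see resample_trace)",
      ncol(data$windows), base$spec$window_len, base$spec$window_len))
  spec <- base$spec
  spec$dense_dropout <- cfg$dropout_rate
  sp <- split_training_set(data, cfg$split_fraction, cfg$seed)
  fit <- .nn_train(base$params, spec_for_cpp(spec),
                   data$windows[sp$train_idx, , drop = FALSE],
                   as.numeric(data$labels[sp$train_idx]),
                   data$windows[sp$val_idx, , drop = FALSE],
                   as.numeric(data$labels[sp$val_idx]),
                   cfg$learning_rate, cfg$batch_size, cfg$max_epochs,
                   cfg$early_stop_patience, cfg$seed, cfg$freeze_conv,
                   "val_loss", verbose)
  out <- base
  out$params <- fit$params
  out$history <- fit$history
  out$config <- cfg
  out$frozen <- isTRUE(cfg$freeze_conv)
  out$trained <- TRUE
  out$best_epoch <- fit$best_epoch
  out
}
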