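# Independent R reference implementation of the classifier forward pass
# (inference mode). Deliberately naive: direct loops over kernel offsets and
# timesteps, no shared code with the C++ engine. Used as the oracle for the
# network's numerics on tiny architectures.

ref_conv_same <- function(X, W, b) {
  # X: T x Cin, W: (k*Cin) x Cout (kernel-major rows: offset j, channel c at
  # row j*Cin + c), b: Cout
  Tn <- nrow(X); Cin <- ncol(X); Cout <- ncol(W)
  k <- nrow(W) / Cin
  pad <- (k - 1) / 2
  out <- matrix(0, Tn, Cout)
  for (t in seq_len(Tn)) {
    acc <- b
    for (j in seq_len(k)) {
      ts <- t + (j - 1) - pad
      if (ts >= 1 && ts <= Tn)
        acc <- acc + X[ts, , drop = FALSE] %*% W[((j - 1) * Cin + 1):(j * Cin), , drop = FALSE]
    }
    out[t, ] <- acc
  }
  out
}

ref_forward <- function(params, spec, x) {
  # x: single window (numeric vector); returns scalar score. float32 effects
  # are ignored, so agreement with the C++ engine is ~1e-4 relative.
  eps <- 1e-3
  A <- matrix(x, ncol = 1)
  cin <- 1L
  for (i in seq_along(spec$filters)) {
    W <- params[[sprintf("conv%d_W", i)]]
    b <- as.numeric(params[[sprintf("conv%d_b", i)]])
    Z <- ref_conv_same(A, W, b)
    g <- as.numeric(params[[sprintf("bn%d_gamma", i)]])
    be <- as.numeric(params[[sprintf("bn%d_beta", i)]])
    rm <- as.numeric(params[[sprintf("bn%d_rmean", i)]])
    rv <- as.numeric(params[[sprintf("bn%d_rvar", i)]])
    Z <- sweep(sweep(Z, 2, rm), 2, sqrt(rv + eps), "/")
    Z <- sweep(sweep(Z, 2, g, "*"), 2, be, "+")
    Z <- ifelse(Z >= 0, Z, spec$leaky_alpha * Z)
    p <- spec$pools[i]
    if (p > 0) {
      T2 <- nrow(Z) %/% p
      Z <- t(vapply(seq_len(T2), function(t2)
        colMeans(Z[((t2 - 1) * p + 1):(t2 * p), , drop = FALSE]), numeric(ncol(Z))))
      if (ncol(A) == 1 && is.null(dim(Z))) Z <- matrix(Z, ncol = spec$filters[i])
    }
    A <- Z
    cin <- spec$filters[i]
  }
  U <- spec$lstm_units
  sigm <- function(z) 1 / (1 + exp(-z))
  run_lstm <- function(dir) {
    Wx <- params[[sprintf("lstm_%s_Wx", dir)]]
    Wh <- params[[sprintf("lstm_%s_Wh", dir)]]
    bb <- as.numeric(params[[sprintf("lstm_%s_b", dir)]])
    h <- numeric(U); cc <- numeric(U)
    steps <- if (dir == "fw") seq_len(nrow(A)) else rev(seq_len(nrow(A)))
    for (t in steps) {
      z <- as.numeric(A[t, ] %*% Wx + h %*% Wh) + bb
      gi <- sigm(z[1:U]); gf <- sigm(z[(U + 1):(2 * U)])
      gg <- tanh(z[(2 * U + 1):(3 * U)]); go <- sigm(z[(3 * U + 1):(4 * U)])
      cc <- gf * cc + gi * gg
      h <- go * tanh(cc)
    }
    h
  }
  h <- run_lstm("fw") + run_lstm("bw")
  z1 <- as.numeric(h %*% params$dense1_W) + as.numeric(params$dense1_b)
  a1 <- ifelse(z1 >= 0, z1, spec$leaky_alpha * z1)
  z2 <- sum(a1 * params$dense2_W) + as.numeric(params$dense2_b)
  sigm(z2)
}
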