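# Minimal CNN engine. Activations are channels-first matrices
# (C x H*W*N, columns ordered h, then w, then sample); convolutions gather
# im2col patches and run BLAS GEMMs in C++ (src/kernels.cpp); gradients are
# exact analytic adjoints, verified against finite differences in the test
# suite. Batch-norm statistics are per row, so no transposes are needed
# anywhere in the hot path.

# (H, W, C, N) array -> channels-first matrix
to_channels_first <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(3, 1, 2, 4)), d[3])
}

conv_forward <- function(x, H, W, N, W_mat, b, k) {
  .conv_fwd_c(x, H, W, N, k, W_mat, b)
}

conv_backward <- function(x, dy, H, W, N, W_mat, k, want_dx = TRUE) {
  .conv_bwd_c(x, dy, H, W, N, k, W_mat, want_dx)
}

# batch normalization per channel (= per row)
bn_forward <- function(x, gamma, beta, state, train, momentum = 0.1,
                       eps = 1e-5) {
  if (train) {
    mu <- rowMeans(x)
    vv <- rowMeans(x * x) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * vv
  } else {
    mu <- state$running_mean
    vv <- state$running_var
  }
  ivar <- 1 / sqrt(vv + eps)
  xhat <- (x - mu) * ivar
  y <- xhat * gamma + beta
  list(out = y, state = state,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma, train = train))
}

bn_backward <- function(dy, cache) {
  m <- ncol(dy)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  g_ivar <- cache$gamma * cache$ivar
  if (cache$train) {
    dx <- (dy - dbeta / m - cache$xhat * (dgamma / m)) * g_ivar
  } else {
    dx <- dy * g_ivar
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_cross_entropy <- function(logits, y) {
  # logits: n_classes x N; y: 0-based integer labels
  n <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  idx <- cbind(y + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

adam_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
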