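#' Multi-scale kernel CNN configuration
#'
#' The classifier stacks convolution blocks sharing one structure: parallel
#' convolutions with distinct (odd) kernel sizes and same-padding, channel
#' concatenation of the branch outputs, a 1x1 convolution fusing them back to
#' the block's output width, batch normalization and ReLU. No pooling is
#' used, so the spatial size is preserved end to end; a single fully
#' connected layer maps the flattened last block to class logits. The default
#' configuration is four blocks of 16, 32, 64 and 128 channels with kernel
#' sizes 5 and 7.
#'
#' @param kernel_sizes Integer vector of odd kernel sizes, subset of common
#'   choices 3/5/7 (default `c(5, 7)`).
#' @param block_channels Output channels of each block (default
#'   `c(16, 32, 64, 128)`).
#' @param n_classes 2 (binary) or 4 (four-class).
#' @param input_shape `(height, width, depth)` of one sample (default
#'   `c(18, 18, 6)`).
#' @return A `model_config` list.
#' @export
model_config <- function(kernel_sizes = c(5, 7),
                         block_channels = c(16, 32, 64, 128),
                         n_classes = 2, input_shape = c(18, 18, 6)) {
  kernel_sizes <- sort(unique(as.integer(kernel_sizes)))
  if (length(kernel_sizes) == 0) stopf("need at least one kernel size")
  if (any(kernel_sizes %% 2L == 0L))
    stopf("kernel sizes must be odd (same-padding symmetry): %s",
          paste(kernel_sizes[kernel_sizes %% 2L == 0L], collapse = ", "))
  if (!n_classes %in% c(2L, 4L)) stopf("n_classes must be 2 or 4")
  if (any(block_channels < 1)) stopf("block_channels must be positive")
  structure(list(kernel_sizes = kernel_sizes,
                 block_channels = as.integer(block_channels),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape)),
            class = "model_config")
}

param_names_block <- function(i, kernel_sizes) {
  c(unlist(lapply(kernel_sizes, function(k)
    paste0("b", i, "_k", k, "_", c("W", "b")))),
    paste0("b", i, "_fuse_", c("W", "b")),
    paste0("b", i, "_bn_", c("gamma", "beta")))
}

#' Build a multi-scale kernel CNN
#'
#' Initializes all weights with variance-scaling (fan-in) Gaussian draws from
#' a seeded stream; biases start at zero, batch-norm scale/shift at 1/0.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `mscnn_model`: configuration, parameter list and batch-norm
#'   running statistics.
#' @export
#' @examples
#' m <- build_model(model_config(block_channels = c(8, 16)))
#' count_params(m)
build_model <- function(config, seed = 1) {
  set.seed(as.integer(seed))
  params <- list()
  bn_states <- list()
  cin <- config$input_shape[3]
  for (i in seq_along(config$block_channels)) {
    cout <- config$block_channels[i]
    for (k in config$kernel_sizes) {
      fan_in <- k * k * cin
      params[[paste0("b", i, "_k", k, "_W")]] <-
        matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
      params[[paste0("b", i, "_k", k, "_b")]] <- numeric(cout)
    }
    cat_c <- length(config$kernel_sizes) * cout
    params[[paste0("b", i, "_fuse_W")]] <-
      matrix(rnorm(cout * cat_c, sd = sqrt(2 / cat_c)), cout, cat_c)
    params[[paste0("b", i, "_fuse_b")]] <- numeric(cout)
    params[[paste0("b", i, "_bn_gamma")]] <- rep(1, cout)
    params[[paste0("b", i, "_bn_beta")]] <- numeric(cout)
    bn_states[[i]] <- list(running_mean = numeric(cout),
                           running_var = rep(1, cout))
    cin <- cout
  }
  d_fc <- prod(config$input_shape[1:2]) * cin
  params$fc_W <- matrix(rnorm(config$n_classes * d_fc, sd = sqrt(2 / d_fc)),
                        config$n_classes, d_fc)
  params$fc_b <- numeric(config$n_classes)
  structure(list(config = config, params = params, bn_states = bn_states,
                 seed = as.integer(seed)),
            class = "mscnn_model")
}

#' @export
print.mscnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mscnn_model> %d blocks (channels %s), kernels {%s}, %d classes, input %s\n",
              length(cfg$block_channels),
              paste(cfg$block_channels, collapse = ","),
              paste(cfg$kernel_sizes, collapse = ","),
              cfg$n_classes, paste(cfg$input_shape, collapse = "x")))
  cat(sprintf("  %d trainable parameters\n", count_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `mscnn_model`.
#' @return Integer count over convolution, batch-norm and FC parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# forward pass on a channels-first batch; returns logits (n_classes x N),
# per-block caches (inputs to each layer) and updated bn states
mscnn_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  p <- model$params
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  N <- ncol(x) / (H * W)
  caches <- vector("list", length(cfg$block_channels))
  a <- x
  for (i in seq_along(cfg$block_channels)) {
    branches <- lapply(cfg$kernel_sizes, function(k)
      conv_forward(a, H, W, N, p[[paste0("b", i, "_k", k, "_W")]],
                   p[[paste0("b", i, "_k", k, "_b")]], k))
    cat_a <- do.call(rbind, branches)
    fuse <- conv_forward(cat_a, H, W, N, p[[paste0("b", i, "_fuse_W")]],
                         p[[paste0("b", i, "_fuse_b")]], 1L)
    bn <- bn_forward(fuse, p[[paste0("b", i, "_bn_gamma")]],
                     p[[paste0("b", i, "_bn_beta")]],
                     model$bn_states[[i]], train = train)
    model$bn_states[[i]] <- bn$state
    relu_mask <- bn$out > 0
    a_out <- bn$out * relu_mask
    if (anyNA(a_out) || any(is.infinite(a_out)))
      stopf("non-finite activations in block %d", i)
    caches[[i]] <- list(x_in = a, cat_a = cat_a, bn = bn$cache,
                        relu = relu_mask)
    a <- a_out
  }
  xf <- matrix(a, nrow(a) * H * W, N)
  logits <- p$fc_W %*% xf + p$fc_b
  list(logits = logits, caches = caches, fc_x = xf, last_c = nrow(a),
       H = H, W = W, N = N, bn_states = model$bn_states)
}

mscnn_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  H <- fwd$H; W <- fwd$W; N <- fwd$N
  grads <- list()
  grads$fc_W <- tcrossprod(dlogits, fwd$fc_x)
  grads$fc_b <- rowSums(dlogits)
  da <- matrix(crossprod(p$fc_W, dlogits), fwd$last_c)
  for (i in rev(seq_along(cfg$block_channels))) {
    cache <- fwd$caches[[i]]
    da <- da * cache$relu
    bnb <- bn_backward(da, cache$bn)
    grads[[paste0("b", i, "_bn_gamma")]] <- bnb$dgamma
    grads[[paste0("b", i, "_bn_beta")]] <- bnb$dbeta
    fb <- conv_backward(cache$cat_a, bnb$dx, H, W, N,
                        p[[paste0("b", i, "_fuse_W")]], 1L)
    grads[[paste0("b", i, "_fuse_W")]] <- fb$dW
    grads[[paste0("b", i, "_fuse_b")]] <- fb$db
    cout_i <- cfg$block_channels[i]
    want_dx <- i > 1L  # the input gradient of block 1 is never used
    da_next <- NULL
    for (j in seq_along(cfg$kernel_sizes)) {
      k <- cfg$kernel_sizes[j]
      dbranch <- fb$dx[(j - 1L) * cout_i + seq_len(cout_i), , drop = FALSE]
      cb <- conv_backward(cache$x_in, dbranch, H, W, N,
                          p[[paste0("b", i, "_k", k, "_W")]], k,
                          want_dx = want_dx)
      grads[[paste0("b", i, "_k", k, "_W")]] <- cb$dW
      grads[[paste0("b", i, "_k", k, "_b")]] <- cb$db
      if (want_dx)
        da_next <- if (is.null(da_next)) cb$dx else da_next + cb$dx
    }
    da <- da_next
  }
  grads
}

#' Forward pass: class logits for a batch
#'
#' @param model An `mscnn_model`.
#' @param x Array `(H, W, depth, N)` of samples (or a single `(H, W, depth)`
#'   sample).
#' @param train Use batch statistics in batch norm (`TRUE`) or frozen running
#'   statistics (`FALSE`, default: deterministic evaluation mode).
#' @return `N x n_classes` logit matrix.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!identical(dim(x)[1:3], as.integer(model$config$input_shape)))
    stopf("input shape %s does not match model input %s",
          paste(dim(x)[1:3], collapse = "x"),
          paste(model$config$input_shape, collapse = "x"))
  t(mscnn_forward(model, to_channels_first(x), train = train)$logits)
}

#' Predicted class indices for a batch
#' @param model An `mscnn_model`.
#' @param x Sample array `(H, W, depth, N)`.
#' @param batch_size Evaluation batch size.
#' @return 0-based integer class predictions, length N.
#' @export
predict_classes <- function(model, x, batch_size = 256) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  out <- integer(n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    lg <- model_forward(model, x[, , , idx, drop = FALSE], train = FALSE)
    out[idx] <- max.col(lg) - 1L
  }
  out
}
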