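#' Training configuration
#'
#' The optimization protocol: Adam, cosine-annealed learning rate starting at
#' `lr_init` and ending at `lr_init * lr_final_fraction` at the last epoch,
#' softmax cross-entropy (the 2-logit head on binary tasks is the
#' binary cross-entropy in disguise), fixed epoch count, no early stopping,
#' no weight decay. Defaults reproduce the reference protocol: lr 0.001
#' annealed to 0.0001 over 150 epochs, batch size 640, 10 folds.
#'
#' @param lr_init Initial learning rate (default 0.001).
#' @param lr_final_fraction Final lr as a fraction of `lr_init` (default 0.1).
#' @param epochs Training epochs (default 150).
#' @param batch_size Minibatch size (default 640).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed controlling weight init, fold split and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_init = 0.001, lr_final_fraction = 0.1,
                         epochs = 150, batch_size = 640, folds = 10,
                         seed = 1) {
  if (epochs < 1) stopf("epochs must be >= 1")
  structure(list(lr_init = lr_init, lr_final_fraction = lr_final_fraction,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_min + (lr_init - lr_min) (1 + cos(pi e / (E - 1))) / 2` with
#' `lr_min = lr_init * lr_final_fraction`, so the rate starts at `lr_init`
#' and reaches `lr_min` exactly at the last epoch.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param config A [train_config()].
#' @return Learning rate for that epoch.
#' @export
#' @examples
#' cosine_lr(0, train_config())    # 0.001
#' cosine_lr(149, train_config())  # 0.0001
cosine_lr <- function(epoch, config) {
  if (any(epoch < 0 | epoch >= config$epochs))
    stopf("epoch must lie in [0, %d)", config$epochs)
  lr_min <- config$lr_init * config$lr_final_fraction
  if (config$epochs == 1L) return(config$lr_init)
  lr_min + 0.5 * (config$lr_init - lr_min) *
    (1 + cos(pi * epoch / (config$epochs - 1)))
}

#' Random segment-level k-fold partition
#'
#' Splits sample indices into k disjoint folds of sizes differing by at most
#' one, by a seeded random shuffle. Folding is at segment level: segments of
#' one trial may land in different folds, replicating the reference
#' validation scheme (see the vignette for why this leaks trial identity and
#' how to group instead).
#'
#' @param n Number of samples (or a vector whose length is used).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param group Optional grouping factor (length n): all samples of one group
#'   are assigned to the same fold (leakage-free alternative).
#' @return List of k disjoint integer index vectors covering `1:n`.
#' @export
make_folds <- function(n, k = 10, seed = 1, group = NULL) {
  if (length(n) > 1) n <- length(n)
  if (k > n) stopf("k (%d) exceeds sample count (%d)", k, n)
  set.seed(as.integer(seed))
  if (is.null(group)) {
    return(unname(split(sample.int(n), rep_len(seq_len(k), n))))
  }
  g <- as.integer(factor(group))
  ug <- sample(unique(g))
  fold_of_group <- rep(seq_len(k), length.out = length(ug))[match(g, ug)]
  unname(split(seq_len(n), fold_of_group))
}

evaluate_accuracy <- function(model, x, y, batch_size = 256) {
  pred <- predict_classes(model, x, batch_size)
  100 * mean(pred == y)
}

#' Train the model on one train/validation split
#'
#' Runs the full protocol on the training samples (Adam, cosine schedule,
#' per-epoch reshuffling seeded from (seed, epoch), last short batch kept)
#' and evaluates classification accuracy on the validation samples once,
#' after the final epoch.
#'
#' @param x Sample array `(H, W, depth, N)`.
#' @param y 0-based integer labels, length N.
#' @param train_idx,val_idx Disjoint index vectors into the samples.
#' @param mcfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return List: `accuracy` (percent), `model`, `epoch_losses`, `confusion`.
#' @export
train_one_fold <- function(x, y, train_idx, val_idx, mcfg, tcfg,
                           verbose = FALSE) {
  if (length(intersect(train_idx, val_idx)) > 0)
    stopf("train and validation indices overlap")
  model <- build_model(mcfg, seed = tcfg$seed)
  opt <- adam_state(model$params)
  n_tr <- length(train_idx)
  hw <- prod(dim(x)[1:2])
  x_cf <- to_channels_first(x)  # one conversion; batches are column slices
  cols_of <- function(idx) rep((idx - 1L) * hw, each = hw) + seq_len(hw)
  epoch_losses <- numeric(tcfg$epochs)
  for (e in seq_len(tcfg$epochs) - 1L) {
    lr <- cosine_lr(e, tcfg)
    set.seed(derive_seed(tcfg$seed, e + 1L))
    ord <- sample(train_idx)
    losses <- numeric(0)
    for (at in seq(1L, n_tr, by = tcfg$batch_size)) {
      bi <- ord[at:min(n_tr, at + tcfg$batch_size - 1L)]
      xb <- x_cf[, cols_of(bi), drop = FALSE]
      yb <- y[bi]
      fwd <- mscnn_forward(model, xb, train = TRUE)
      model$bn_states <- fwd$bn_states
      sce <- softmax_cross_entropy(fwd$logits, yb)
      if (!is.finite(sce$loss))
        stopf("training diverged (loss = %g) at epoch %d, lr %g", sce$loss,
              e, lr)
      grads <- mscnn_backward(model, fwd, sce$dlogits)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$state
      losses <- c(losses, sce$loss)
    }
    epoch_losses[e + 1L] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %3d  lr %.6f  loss %.4f", e, lr,
                      epoch_losses[e + 1L]))
  }
  pred <- integer(length(val_idx))
  for (at in seq(1L, length(val_idx), by = 256L)) {
    vi <- val_idx[at:min(length(val_idx), at + 255L)]
    lg <- mscnn_forward(model, x_cf[, cols_of(vi), drop = FALSE],
                        train = FALSE)$logits
    pred[at:(at + length(vi) - 1L)] <- max.col(t(lg)) - 1L
  }
  acc <- 100 * mean(pred == y[val_idx])
  confusion <- table(truth = factor(y[val_idx],
                                    levels = 0:(mcfg$n_classes - 1L)),
                     predicted = factor(pred,
                                        levels = 0:(mcfg$n_classes - 1L)))
  list(accuracy = acc, model = model, epoch_losses = epoch_losses,
       confusion = confusion)
}

#' Segment-level k-fold cross-validation
#'
#' Partitions all samples into k folds, trains k independently initialized
#' models (fold f is validated on fold f, trained on the rest), and reports
#' the per-fold accuracies and their mean.
#'
#' @param x Sample array `(H, W, depth, N)`.
#' @param y 0-based integer labels.
#' @param mcfg A [model_config()].
#' @param tcfg A [train_config()]; `tcfg$folds` and `tcfg$seed` drive the
#'   split.
#' @param group Optional grouping factor for leakage-free folds (see
#'   [make_folds()]).
#' @param verbose Print fold accuracies.
#' @return A `cv_result`: `fold_accuracies`, `mean_accuracy`, `confusions`,
#'   `config` echo.
#' @export
run_cross_validation <- function(x, y, mcfg, tcfg, group = NULL,
                                 verbose = FALSE) {
  n <- dim(x)[4]
  folds <- make_folds(n, tcfg$folds, seed = tcfg$seed, group = group)
  accs <- numeric(length(folds))
  confusions <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    val_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), val_idx)
    fold_tcfg <- tcfg
    fold_tcfg$seed <- derive_seed(tcfg$seed, f)  # independent init per fold
    fit <- train_one_fold(x, y, train_idx, val_idx, mcfg, fold_tcfg)
    accs[f] <- fit$accuracy
    confusions[[f]] <- fit$confusion
    if (verbose) message(sprintf("fold %d: %.2f%%", f, accs[f]))
  }
  structure(list(fold_accuracies = accs, mean_accuracy = mean(accs),
                 confusions = confusions,
                 config = list(model = mcfg, train = tcfg)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean accuracy %.2f%%\n",
              length(x$fold_accuracies), x$mean_accuracy))
  cat("  folds:", paste(sprintf("%.1f", x$fold_accuracies), collapse = " "),
      "\n")
  invisible(x)
}
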