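test_that("cosine annealing hits its endpoints and midpoint exactly", {
  tc <- train_config()  # 150 epochs, lr 0.001 -> 0.0001
  expect_equal(cosine_lr(0, tc), 0.001, tolerance = 1e-12)
  expect_equal(cosine_lr(149, tc), 0.0001, tolerance = 1e-12)
  # cos(pi/2) = 0 at the midpoint of 0..148
  expect_equal(cosine_lr(74.5, tc), (0.001 + 0.0001) / 2, tolerance = 1e-12)
  expect_error(cosine_lr(150, tc), "epoch")
  expect_error(cosine_lr(-1, tc), "epoch")
  # monotone decreasing across the schedule
  lrs <- vapply(0:149, cosine_lr, numeric(1), config = tc)
  expect_true(all(diff(lrs) < 0))
})

test_that("folds form a seeded partition with near-equal sizes", {
  folds <- make_folds(12800, 10, seed = 42)
  expect_length(folds, 10L)
  expect_true(all(vapply(folds, length, integer(1)) == 1280L))
  expect_identical(sort(unlist(folds)), 1:12800)
  expect_identical(make_folds(12800, 10, seed = 42), folds)
  expect_false(identical(make_folds(12800, 10, seed = 43), folds))
  # non-divisible case: sizes differ by at most one
  f7 <- make_folds(100, 7, seed = 1)
  expect_identical(sort(unlist(f7)), 1:100)
  expect_lte(diff(range(vapply(f7, length, integer(1)))), 1L)
  expect_error(make_folds(5, 10), "exceeds")
})

test_that("grouped folds keep all segments of a trial together", {
  group <- rep(1:20, each = 10)
  folds <- make_folds(200, 5, seed = 3, group = group)
  expect_identical(sort(unlist(folds)), 1:200)
  for (f in folds) expect_true(all(table(group[f]) == 10))
})

test_that("a constant-prediction model scores exactly at chance", {
  cfg <- model_config(c(3), c(2), n_classes = 2, input_shape = c(9, 9, 6))
  m <- build_model(cfg, seed = 1)
  m$params$fc_W[] <- 0
  m$params$fc_b <- c(5, 0)  # always predicts class 0
  x <- array(runif(9 * 9 * 6 * 40), c(9, 9, 6, 40))
  y <- rep(c(0L, 1L), 20)
  expect_equal(msceeg:::evaluate_accuracy(m, x, y), 50)
  y4 <- rep(0:3, 10)
  cfg4 <- model_config(c(3), c(2), n_classes = 4, input_shape = c(9, 9, 6))
  m4 <- build_model(cfg4, seed = 1)
  m4$params$fc_W[] <- 0
  m4$params$fc_b <- c(5, 0, 0, 0)
  expect_equal(msceeg:::evaluate_accuracy(m4, x, y4), 25)
})

test_that("training reduces the loss and recovers a separable signal", {
  # two classes differing by a localized mean shift in one depth slice
  set.seed(55)
  n <- 120
  x <- array(runif(9 * 9 * 6 * n, 0, 0.3), c(9, 9, 6, n))
  y <- rep(c(0L, 1L), n / 2)
  x[3:5, 3:5, 2, y == 1L] <- x[3:5, 3:5, 2, y == 1L] + 0.6
  cfg <- model_config(c(3), c(4), n_classes = 2, input_shape = c(9, 9, 6))
  tcfg <- train_config(epochs = 25, batch_size = 32, folds = 2, seed = 2)
  fit <- train_one_fold(x, y, 1:100, 101:120, cfg, tcfg)
  expect_lt(tail(fit$epoch_losses, 1), fit$epoch_losses[1])
  expect_gte(fit$accuracy, 90)
  expect_identical(sum(fit$confusion), 20L)
})

test_that("cross-validation reports one accuracy per fold plus their mean", {
  set.seed(77)
  n <- 60
  x <- array(runif(9 * 9 * 6 * n, 0, 0.3), c(9, 9, 6, n))
  y <- rep(c(0L, 1L), n / 2)
  x[2:4, 2:4, 1, y == 1L] <- x[2:4, 2:4, 1, y == 1L] + 0.6
  cfg <- model_config(c(3), c(2), n_classes = 2, input_shape = c(9, 9, 6))
  tcfg <- train_config(epochs = 4, batch_size = 20, folds = 3, seed = 4)
  cv <- run_cross_validation(x, y, cfg, tcfg)
  expect_length(cv$fold_accuracies, 3L)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 100))
})

test_that("train/validation overlap is rejected", {
  x <- array(0, c(9, 9, 6, 10))
  cfg <- model_config(c(3), c(2), input_shape = c(9, 9, 6))
  expect_error(train_one_fold(x, rep(0L, 10), 1:6, 5:10, cfg, train_config()),
               "overlap")
})

test_that("the ablation harness emits one row per grid point", {
  trials <- small_synth_trials()
  mcfg <- model_config(c(3), c(2), n_classes = 2)
  tcfg <- train_config(epochs = 2, batch_size = 30, folds = 2, seed = 6)
  spec <- segment_spec(active_s = 10, n_segments = 5)
  tab <- run_ablation("bands", list("raw", c("beta", "gamma")), trials,
                      mcfg, tcfg, spec = spec)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$point, c("raw", "beta+gamma"))
  expect_true(all(is.finite(tab$mean_accuracy)))
  ktab <- run_ablation("kernels", list(c(3), c(3, 5)), trials, mcfg, tcfg,
                       spec = spec, bands = "raw")
  expect_identical(nrow(ktab), 2L)
  # an invalid grid point is skipped with a warning, not fatal
  expect_warning(
    bad <- run_ablation("bands", list("raw", "nosuch"), trials, mcfg, tcfg,
                        spec = spec),
    "skipped")
  expect_true(is.na(bad$mean_accuracy[2]))
})
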