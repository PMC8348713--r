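test_that("a block concatenates branches and fuses back to out_channels", {
  cfg <- model_config(kernel_sizes = c(5, 7), block_channels = c(16),
                      n_classes = 2, input_shape = c(18, 18, 6))
  m <- build_model(cfg, seed = 1)
  # branch weights map 6 -> 16 each; fusion maps 32 -> 16
  expect_identical(dim(m$params$b1_k5_W), c(16L, 5L * 5L * 6L))
  expect_identical(dim(m$params$b1_k7_W), c(16L, 7L * 7L * 6L))
  expect_identical(dim(m$params$b1_fuse_W), c(16L, 32L))
  x <- array(runif(18 * 18 * 6 * 3), c(18, 18, 6, 3))
  expect_identical(dim(model_forward(m, x)), c(3L, 2L))
})

test_that("spatial size is preserved with no pooling for all kernel sets", {
  table3 <- list(3, 5, 7, c(3, 5), c(3, 7), c(5, 7), c(3, 5, 7))
  x <- array(runif(18 * 18 * 6 * 2), c(18, 18, 6, 2))
  for (ks in table3) {
    cfg <- model_config(kernel_sizes = ks, block_channels = c(4, 6),
                        n_classes = 4, input_shape = c(18, 18, 6))
    m <- build_model(cfg, seed = 2)
    fwd <- msceeg:::mscnn_forward(m, msceeg:::to_channels_first(x))
    # logits exist => the 18x18 spatial grid survived both blocks into the FC
    expect_identical(dim(fwd$logits), c(4L, 2L))
    expect_identical(dim(m$params$fc_W)[2], 18L * 18L * 6L)
  }
})

test_that("the logit head matches the task and input shape re-derives", {
  x2 <- array(runif(9 * 9 * 6 * 5), c(9, 9, 6, 5))
  cfg <- model_config(block_channels = c(4), n_classes = 2,
                      input_shape = c(9, 9, 6))
  expect_identical(dim(model_forward(build_model(cfg), x2)), c(5L, 2L))
  cfg4 <- model_config(block_channels = c(4), n_classes = 4,
                       input_shape = c(9, 9, 6))
  expect_identical(dim(model_forward(build_model(cfg4), x2)), c(5L, 4L))
  expect_error(model_forward(build_model(cfg),
                             array(0, c(18, 18, 6, 2))), "input shape")
})

test_that("parameter count equals the hand-expanded closed form", {
  for (ks in list(c(5, 7), c(3), c(3, 5, 7))) {
    bc <- c(16, 32, 64, 128)
    cfg <- model_config(kernel_sizes = ks, block_channels = bc,
                        n_classes = 2, input_shape = c(18, 18, 6))
    m <- build_model(cfg, seed = 1)
    expected <- 0
    cin <- 6
    for (cout in bc) {
      for (k in ks) expected <- expected + k * k * cin * cout + cout
      expected <- expected + length(ks) * cout * cout + cout  # 1x1 fusion
      expected <- expected + 2 * cout                         # batch norm
      cin <- cout
    }
    expected <- expected + (18 * 18 * cin) * 2 + 2            # FC head
    expect_identical(count_params(m), as.integer(expected))
  }
})

test_that("capacity grows with kernel count and block width", {
  base <- count_params(build_model(model_config(c(5), c(8, 16))))
  more_k <- count_params(build_model(model_config(c(5, 7), c(8, 16))))
  wider <- count_params(build_model(model_config(c(5), c(16, 16))))
  expect_gt(more_k, base)
  expect_gt(wider, base)
})

test_that("even kernel sizes and bad class counts are rejected", {
  expect_error(model_config(kernel_sizes = c(4)), "odd")
  expect_error(model_config(n_classes = 3), "n_classes")
  expect_error(model_config(kernel_sizes = integer(0)), "at least one")
})

test_that("forward is deterministic in evaluation mode", {
  cfg <- model_config(c(5, 7), c(4), n_classes = 2,
                      input_shape = c(9, 9, 6))
  m <- build_model(cfg, seed = 7)
  x1 <- array(runif(9 * 9 * 6), c(9, 9, 6))
  batch <- array(c(x1, x1), c(9, 9, 6, 2))
  lg <- model_forward(m, batch)
  expect_identical(lg[1, ], lg[2, ])  # duplicated sample, identical logits
  expect_identical(model_forward(m, batch), lg)  # rerun, bitwise equal
  # rebuilt with the same seed, identical weights
  m2 <- build_model(cfg, seed = 7)
  expect_identical(m$params, m2$params)
})

test_that("zero input with a zero FC layer yields zero logits", {
  cfg <- model_config(c(3), c(4), n_classes = 2, input_shape = c(9, 9, 6))
  m <- build_model(cfg, seed = 1)
  m$params$fc_W[] <- 0
  m$params$fc_b[] <- 0
  lg <- model_forward(m, array(0, c(9, 9, 6, 2)))
  expect_true(all(lg == 0))
})

test_that("the C++ convolution agrees with a naive reference", {
  set.seed(21)
  for (k in c(1L, 3L, 5L, 7L)) {
    H <- 7L; W <- 6L; N <- 3L; C <- 4L; cout <- 5L
    x <- matrix(rnorm(C * H * W * N), C)
    Wm <- matrix(rnorm(cout * C * k * k), cout)
    b <- rnorm(cout)
    got <- msceeg:::.conv_fwd_c(x, H, W, N, k, Wm, b)
    expect_equal(got, oracle_conv(x, H, W, N, k, Wm, b), tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(31)
  cfg <- model_config(kernel_sizes = c(3, 5), block_channels = c(3, 4),
                      n_classes = 2, input_shape = c(6, 6, 2))
  m <- build_model(cfg, seed = 3)
  x <- msceeg:::to_channels_first(array(runif(6 * 6 * 2 * 5), c(6, 6, 2, 5)))
  y <- c(0L, 1L, 0L, 1L, 1L)
  lossfn <- function(mm) {
    fwd <- msceeg:::mscnn_forward(mm, x, train = TRUE)
    msceeg:::softmax_cross_entropy(fwd$logits, y)$loss
  }
  fwd <- msceeg:::mscnn_forward(m, x, train = TRUE)
  sce <- msceeg:::softmax_cross_entropy(fwd$logits, y)
  gr <- msceeg:::mscnn_backward(m, fwd, sce$dlogits)
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})
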