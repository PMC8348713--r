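test_that("differential entropy matches the Gaussian closed form", {
  # biased variance of [1,-1,1,-1] is exactly 1
  expect_equal(differential_entropy(c(1, -1, 1, -1)),
               0.5 * log(2 * pi * exp(1)))
  expect_equal(differential_entropy(c(1, -1, 1, -1)), 1.41894,
               tolerance = 1e-5)
  # scaling by c adds log|c| exactly
  set.seed(4)
  x <- rnorm(500)
  expect_equal(differential_entropy(3 * x) - differential_entropy(x),
               log(3), tolerance = 1e-12)
  # Monte-Carlo consistency: standard normal draws approach 1/2 log(2 pi e)
  set.seed(11)
  z <- rnorm(1e5)
  expect_equal(differential_entropy(z), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.01)
})

test_that("the histogram plug-in estimator approximates the closed form", {
  set.seed(23)
  x <- rnorm(2e4, sd = 3)
  hist_de <- differential_entropy(x, method = "histogram")
  gauss_de <- differential_entropy(x)
  expect_equal(hist_de, gauss_de, tolerance = 0.05)
  expect_equal(gauss_de, 0.5 * log(2 * pi * exp(1) * 9), tolerance = 0.05)
})

test_that("zero-variance segments floor the entropy with a warning", {
  expect_warning(de <- differential_entropy(rep(2, 10)), "floored")
  expect_true(is.finite(de))
})

test_that("elementary features reproduce hand-computed examples", {
  expect_equal(seg_mean(c(1, 3, 6)), 10 / 3)
  expect_equal(seg_mean_d1(c(1, 3, 6)), 2.5)          # (2 + 3) / 2
  expect_equal(seg_mean_d1(c(1, 3, 6)), (6 - 1) / 2)  # telescoped form
  expect_equal(seg_mean_d2(c(1, 3, 6, 10)), 6)        # ((6-1) + (10-3)) / 2
  expect_equal(seg_var(c(2, 2, 2)), 0)
  expect_equal(seg_std(c(2, 2, 2)), 0)
  expect_error(seg_mean(c(1, 2)), "length >= 3")
})

test_that("each feature matches its brute-force oracle on random segments", {
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(sample(10:200, 1), mean = runif(1, -5, 5),
               sd = runif(1, 0.1, 10))
    expect_equal(seg_mean(x), oracle_mean(x), tolerance = 1e-12)
    expect_equal(seg_mean_d1(x), oracle_mean_d1(x), tolerance = 1e-12)
    expect_equal(seg_mean_d2(x), oracle_mean_d2(x), tolerance = 1e-12)
    expect_equal(seg_var(x), oracle_var(x), tolerance = 1e-12)
    expect_equal(seg_std(x), oracle_std(x), tolerance = 1e-12)
    expect_equal(differential_entropy(x), oracle_de(x), tolerance = 1e-12)
    v <- msceeg:::segment_feature_vector(x)
    expect_equal(unname(v), c(oracle_de(x), oracle_mean(x), oracle_mean_d1(x),
                              oracle_mean_d2(x), oracle_std(x), oracle_var(x)),
                 tolerance = 1e-12)
  }
})

test_that("shift and scale behave as the closed forms dictate", {
  set.seed(9)
  x <- rnorm(300)
  shifted <- msceeg:::segment_feature_vector(x + 7)
  base <- msceeg:::segment_feature_vector(x)
  expect_equal(shifted["mean"], base["mean"] + 7)
  for (f in c("de", "mean_d1", "mean_d2", "std", "var"))
    expect_equal(shifted[f], base[f], tolerance = 1e-9)
  scaled <- msceeg:::segment_feature_vector(2 * x)
  expect_equal(scaled[["std"]], 2 * base[["std"]])
  expect_equal(scaled[["var"]], 4 * base[["var"]])
  expect_equal(scaled[["de"]], base[["de"]] + log(2))
})

test_that("extraction fills the full (segment, channel, band, feature) grid", {
  set.seed(10)
  segs <- lapply(1:4, function(i) matrix(rnorm(3 * 50), 3))
  bands <- list(theta = segs, alpha = segs, beta = segs, gamma = segs)
  arr <- extract_features(bands)
  expect_identical(dim(arr), c(4L, 3L, 4L, 6L))
  expect_false(anyNA(arr))
  # identical segments give identical feature rows
  expect_equal(arr[1, , "theta", ], arr[1, , "gamma", ])
  raw <- extract_features(list(raw = segs))
  expect_identical(dim(raw), c(4L, 3L, 1L, 6L))
})

test_that("trial normalization maps each group onto [0, 1]", {
  vals <- array(0, c(3, 1, 1, 1))
  vals[, 1, 1, 1] <- c(2, 4, 6)
  out <- normalize_trial(vals)
  expect_equal(as.vector(out), c(0, 0.5, 1))
  # constant group collapses to zero with a warning
  cvals <- array(3, c(3, 1, 1, 1))
  expect_warning(cout <- normalize_trial(cvals), "constant")
  expect_equal(as.vector(cout), c(0, 0, 0))
})

test_that("normalization is idempotent and groups span [0, 1]", {
  set.seed(13)
  arr <- array(rnorm(5 * 4 * 2 * 6, sd = 10), c(5, 4, 2, 6))
  norm1 <- normalize_trial(arr)
  expect_true(all(norm1 >= 0 & norm1 <= 1))
  for (b in 1:2) for (f in 1:6) {
    expect_equal(min(norm1[, , b, f]), 0)
    expect_equal(max(norm1[, , b, f]), 1)
  }
  expect_equal(normalize_trial(norm1), norm1)
})
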