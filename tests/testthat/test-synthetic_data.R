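test_that("generation is reproducible from the seed, independent of order", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 3,
                      trial_duration_s = 4, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(lapply(a, `[[`, "signal"), lapply(b, `[[`, "signal"))
  # regenerating one trial in isolation matches its in-dataset copy
  cls <- msceeg:::subject_classes(cfg, 2)
  solo <- generate_trial(cfg, 2, 3, cls[3])
  expect_identical(solo$signal, a[[6]]$signal)
  expect_identical(solo$ratings, a[[6]]$ratings)
})

test_that("band-limited noise concentrates its power inside the band", {
  set.seed(1)
  x <- synth_band_noise(8192, 128, 8, 14, n_series = 4)
  for (j in 1:4) {
    # Welch-style averaged periodogram over 8 segments
    segs <- split(x[, j], rep(1:8, each = 1024))
    psd <- Reduce(`+`, lapply(segs, function(s) Mod(fft(s))^2)) / 8
    freq <- (0:1023) * 128 / 1024
    inband <- sum(psd[freq >= 7.5 & freq <= 14.5])
    expect_gt(inband / sum(psd[freq <= 64]), 0.90)
  }
  expect_equal(sd(x[, 1]), 1, tolerance = 0.1)
})

test_that("1/f noise has decaying spectrum and unit variance", {
  set.seed(2)
  x <- synth_pink_noise(16384, 128, alpha = 1, n_series = 2)
  expect_equal(apply(x, 2, sd), c(1, 1), tolerance = 0.15)
  psd <- Mod(fft(x[, 1]))^2
  freq <- (0:16383) * 128 / 16384
  lo <- mean(psd[freq > 1 & freq < 4])
  hi <- mean(psd[freq > 40 & freq < 60])
  expect_gt(lo / hi, 5)  # roughly 1/f over a decade+
})

test_that("grid-adjacent electrodes correlate more than remote ones", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 6,
                      trial_duration_s = 8, spatial_smoothness = 0.7,
                      effect_size = 0, seed = 31)
  trials <- generate_dataset(cfg)
  d <- msceeg:::layout_grid_distance(default_layout())
  d <- d[deap_channels(), deap_channels()]
  adj <- far <- 0
  for (tr in trials) {
    C <- cor(t(tr$signal))
    adj <- adj + mean(C[d == 1])
    far <- far + mean(C[d >= 4])
  }
  expect_gt(adj / length(trials), far / length(trials))
  expect_gt(adj / length(trials), 0.15)
  expect_lt(abs(far / length(trials)), 0.1)
})

test_that("effect_size = 0 yields label-independent band power", {
  cfg <- synth_config(n_subjects = 5, n_trials_per_subject = 40,
                      trial_duration_s = 5, effect_size = 0, seed = 17)
  trials <- generate_dataset(cfg)
  eff <- match(cfg$effect_channels, deap_channels())
  pw <- vapply(trials, function(tr) mean(tr$signal[eff, ]^2), numeric(1))
  cls <- vapply(trials, function(tr)
    as.integer(tr$ratings[["arousal"]] > 5), integer(1))
  expect_gt(t.test(pw[cls == 1], pw[cls == 0])$p.value, 0.01)
})

test_that("effect_size = 1 separates gamma power by class on the target group",
{
  cfg <- synth_config(n_subjects = 5, n_trials_per_subject = 40,
                      trial_duration_s = 5, effect_size = 1, seed = 19)
  trials <- generate_dataset(cfg)
  eff <- match(cfg$effect_channels, deap_channels())
  gamma_power <- function(tr) {
    g <- apply_filterbank(tr$signal[eff, , drop = FALSE],
                          tr$sampling_rate_hz,
                          band_definitions()["gamma"])$gamma
    mean(g^2)
  }
  pw <- vapply(trials, gamma_power, numeric(1))
  cls <- vapply(trials, function(tr)
    as.integer(tr$ratings[["arousal"]] > 5), integer(1))
  # probability that a high trial out-powers a low trial (ordering AUC)
  auc <- mean(outer(pw[cls == 1], pw[cls == 0], ">"))
  expect_gt(auc, 0.95)
})

test_that("ratings encode the injected class consistently", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 10,
                      trial_duration_s = 2, seed = 23)
  for (s in 1:2) {
    cls <- msceeg:::subject_classes(cfg, s)
    trials <- generate_subject(cfg, s)
    lab_a <- vapply(trials, function(tr)
      label_for_task(tr$ratings, "arousal_binary"), integer(1))
    lab_v <- vapply(trials, function(tr)
      label_for_task(tr$ratings, "valence_binary"), integer(1))
    expect_identical(lab_a, cls)
    expect_identical(lab_v, cls)
    expect_identical(sum(cls), 5L)  # balanced
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(trial_duration_s = 1 / 3), "integer sample")
  expect_error(synth_config(effect_size = -1), "effect_size")
  expect_error(synth_config(effect_size = 3), "effect_size")
  expect_error(synth_config(spatial_smoothness = 2), "spatial_smoothness")
  expect_error(synth_config(effect_channels = c("F3", "XX")), "XX")
})
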