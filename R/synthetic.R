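#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the statistical structure the pipeline exploits,
#' not physiological EEG: per-band band-limited oscillations, 1/f^alpha
#' background noise, spatial correlation between grid-adjacent electrodes
#' (a shared regional source mixed with per-electrode noise), and a
#' class-dependent power modulation concentrated in the Beta and Gamma bands
#' on a designated (default frontal) electrode group. Each trial also carries
#' ratings drawn so the binary labels match the injected class.
#'
#' Band amplitudes are deterministic given the configuration: trials of the
#' same class differ only in their noise realization, so at `effect_size = 0`
#' there is no learnable trial- or class-linked structure at all.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_subject Trials per subject (DEAP layout uses 40).
#' @param sampling_rate_hz Sampling rate (default 128 Hz).
#' @param trial_duration_s Trial length in seconds including the 3 s baseline
#'   (default 63).
#' @param band_powers Named amplitudes (theta, alpha, beta, gamma) of the
#'   band-limited oscillations, arbitrary units (microvolt-scale).
#' @param noise_amplitude Amplitude of the 1/f background noise.
#' @param effect_size Multiplicative class effect e >= 0: on the designated
#'   electrodes the Beta/Gamma oscillation amplitude is scaled by `(1 + e)`
#'   for the high class and `(1 - 0.5 e)` for the low class. Must be <= 2.
#' @param effect_bands Bands carrying the class effect (default beta, gamma).
#' @param effect_channels Designated electrode group (default frontal:
#'   F3, F4, Fz, FC1, FC2).
#' @param spatial_smoothness Mixing weight in \[0, 1\] between the shared
#'   regional source and per-electrode noise; larger values mean stronger
#'   correlation between grid-adjacent electrodes.
#' @param noise_exponent Exponent alpha of the 1/f^alpha background.
#' @param seed Integer seed; every subject/trial derives its own stream from
#'   it, so any subset regenerates identically regardless of order.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 32, n_trials_per_subject = 40,
                         sampling_rate_hz = 128, trial_duration_s = 63,
                         band_powers = c(theta = 1, alpha = 1,
                                         beta = 1, gamma = 1),
                         noise_amplitude = 1,
                         effect_size = 1,
                         effect_bands = c("beta", "gamma"),
                         effect_channels = c("F3", "F4", "Fz", "FC1", "FC2"),
                         spatial_smoothness = 0.7,
                         noise_exponent = 1,
                         seed = 1) {
  n_samples <- trial_duration_s * sampling_rate_hz
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stopf("trial_duration_s x sampling_rate_hz must be an integer sample count")
  if (effect_size < 0 || effect_size > 2)
    stopf("effect_size must lie in [0, 2]")
  if (spatial_smoothness < 0 || spatial_smoothness > 1)
    stopf("spatial_smoothness must lie in [0, 1]")
  if (!all(effect_channels %in% deap_channels()))
    stopf("unknown effect channels: %s",
          paste(setdiff(effect_channels, deap_channels()), collapse = ", "))
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    sampling_rate_hz = sampling_rate_hz,
    trial_duration_s = trial_duration_s,
    band_powers = band_powers,
    noise_amplitude = noise_amplitude,
    effect_size = effect_size,
    effect_bands = effect_bands,
    effect_channels = effect_channels,
    spatial_smoothness = spatial_smoothness,
    noise_exponent = noise_exponent,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# deterministic sub-seed in [0, 2^31) derived from (seed, subject, trial)
derive_seed <- function(seed, subject, trial = 0L) {
  s <- (as.numeric(seed) * 48271 + subject * 30269 + trial * 131) %%
    2147483629
  as.integer(s)
}

#' Band-limited noise (random-phase FFT synthesis)
#'
#' Generates stationary series whose spectrum is flat inside
#' `[low_hz, high_hz]` and exactly zero outside, with unit variance, by the
#' random-phase (surrogate-data) method: every in-band Fourier bin gets unit
#' magnitude and an independent uniform phase, so the time series is
#' asymptotically Gaussian. This is the reference band-limiter used by the
#' synthetic generator; it is independent of the Butterworth filter bank so
#' filter tests are not circular.
#'
#' @param n_samples Series length.
#' @param fs Sampling rate (Hz).
#' @param low_hz,high_hz Band edges (Hz), `0 < low_hz < high_hz <= fs/2`.
#' @param n_series Number of independent series (columns).
#' @return Numeric matrix `n_samples x n_series`.
#' @export
synth_band_noise <- function(n_samples, fs, low_hz, high_hz, n_series = 1) {
  freq <- seq_len(n_samples %/% 2 - 1) * fs / n_samples
  keep <- which(freq >= low_hz & freq <= high_hz)
  spectrum_noise(n_samples, n_series, keep, rep(1, length(keep)))
}

#' 1/f^alpha background noise (FFT synthesis)
#'
#' @param n_samples Series length.
#' @param fs Sampling rate (Hz).
#' @param alpha Spectral exponent (power spectrum proportional to 1/f^alpha).
#' @param n_series Number of independent series.
#' @return Numeric matrix `n_samples x n_series`, unit variance.
#' @export
synth_pink_noise <- function(n_samples, fs, alpha = 1, n_series = 1) {
  freq <- seq_len(n_samples %/% 2 - 1) * fs / n_samples
  spectrum_noise(n_samples, n_series, seq_along(freq), freq^(-alpha / 2))
}

# random-phase spectrum at positive-frequency bins `bins` (1-based index of
# frequency k/n*fs) with magnitudes `mag`, hermitian-symmetrized, inverse FFT,
# scaled to unit variance
spectrum_noise <- function(n, m, bins, mag) {
  Z <- matrix(0 + 0i, n, m)
  Z[bins + 1L, ] <- random_phases(length(bins), m) * mag
  Z[n - bins + 1L, ] <- Conj(Z[bins + 1L, ])
  x <- Re(mvfft(Z, inverse = TRUE)) / n
  # var(x_t) = 2 * sum(mag^2) / n^2 per column
  x * (n / sqrt(2 * sum(mag^2)))
}

random_phases <- function(nb, m) {
  .random_phases_c(as.integer(nb), as.integer(m))
}

# column-normalized neighbourhood mixing matrix: column e averages the base
# field over e and its grid neighbours (Chebyshev distance <= 1), scaled so
# the mixed series keeps unit variance
neighbour_mixing_matrix <- function(layout = default_layout()) {
  d <- layout_grid_distance(layout)
  A <- (d <= 1) * 1.0
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  # reorder to DEAP channel order
  ord <- match(deap_channels(), colnames(A))
  A[ord, ord]
}

#' Generate one synthetic trial
#'
#' @param config A [synth_config()].
#' @param subject_id,trial_id Identifiers; together with `config$seed` they
#'   determine the trial's random stream.
#' @param class 0 (low) or 1 (high): the injected binary class.
#' @return A [trial_record()] whose arousal and valence ratings are consistent
#'   with `class`.
#' @export
generate_trial <- function(config, subject_id, trial_id, class) {
  set.seed(derive_seed(config$seed, subject_id, trial_id))
  fs <- config$sampling_rate_hz
  n <- as.integer(round(config$trial_duration_s * fs))
  bands <- band_definitions()
  A <- neighbour_mixing_matrix()
  w <- config$spatial_smoothness
  eff_idx <- match(config$effect_channels, deap_channels())
  gain <- if (class == 1L) 1 + config$effect_size else
    1 - 0.5 * config$effect_size

  # every component is a linear mix of stationary Gaussian spectra, so the
  # whole trial is assembled in the frequency domain (spatial mixing and the
  # class gain commute with the FFT) and one inverse transform per trial
  # produces the 32-channel signal
  freq <- seq_len(n %/% 2 - 1) * fs / n
  Z <- matrix(0 + 0i, n, 32L)
  mixnorm <- sqrt(w^2 + (1 - w)^2)  # unit variance after shared/private mix
  for (b in names(bands)) {
    bins <- which(freq >= bands[[b]]$low_hz & freq <= bands[[b]]$high_hz)
    nb <- length(bins)
    unit <- n / sqrt(2 * nb)  # unit time-domain variance per field
    Zb <- (w * (random_phases(nb, 32L) %*% A) +
             (1 - w) * random_phases(nb, 32L)) *
      (config$band_powers[[b]] * unit / mixnorm)
    if (b %in% config$effect_bands)
      Zb[, eff_idx] <- Zb[, eff_idx] * gain
    Z[bins + 1L, ] <- Z[bins + 1L, ] + Zb
  }
  mag <- freq^(-config$noise_exponent / 2)
  punit <- n / sqrt(2 * sum(mag^2))
  Z[seq_along(freq) + 1L, ] <- Z[seq_along(freq) + 1L, ] +
    random_phases(length(freq), 32L) * (mag * (config$noise_amplitude * punit))
  Z[n - seq_along(freq) + 1L, ] <- Conj(Z[seq_along(freq) + 1L, ])
  x <- t(Re(mvfft(Z, inverse = TRUE)) / n)
  rownames(x) <- deap_channels()

  hi <- class == 1L
  ratings <- c(
    valence = if (hi) runif(1, 5, 9) else runif(1, 1, 5),
    arousal = if (hi) runif(1, 5, 9) else runif(1, 1, 5),
    dominance = runif(1, 1, 9),
    liking = runif(1, 1, 9)
  )
  trial_record(subject_id, trial_id, x, ratings, sampling_rate_hz = fs)
}

# balanced 0/1 class sequence for one subject, reproducible from config seed
subject_classes <- function(config, subject_id) {
  set.seed(derive_seed(config$seed, subject_id))
  sample(rep(c(0L, 1L), length.out = config$n_trials_per_subject))
}

#' Generate trials for one subject
#' @param config A [synth_config()].
#' @param subject_id Subject index.
#' @return List of [trial_record()]s with a balanced class assignment.
#' @export
generate_subject <- function(config, subject_id) {
  cls <- subject_classes(config, subject_id)
  lapply(seq_len(config$n_trials_per_subject), function(t)
    generate_trial(config, subject_id, t, cls[t]))
}

#' Generate a full synthetic dataset
#'
#' @param config A [synth_config()].
#' @return List of [trial_record()]s,
#'   `n_subjects * n_trials_per_subject` long.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 2,
#'                     trial_duration_s = 7, seed = 42)
#' trials <- generate_dataset(cfg)
#' trials[[1]]
generate_dataset <- function(config) {
  do.call(c, lapply(seq_len(config$n_subjects),
                    function(s) generate_subject(config, s)))
}

#' Write trials to a preprocessed-layout subject file
#'
#' Serializes one subject's trials in the DEAP preprocessed layout
#' (`data`: 40 trials x 40 channels x samples with EEG in channels 1-32 and
#' zeros in the peripheral slots, `labels`: 40 x 4), readable by
#' [load_deap_subject()].
#'
#' @param trials List of [trial_record()]s from one subject.
#' @param path Output file path (`.rds`).
#' @param strict If `TRUE` (default) require exactly 40 trials (the DEAP
#'   layout).
#' @return `path`, invisibly.
#' @export
write_subject_file <- function(trials, path, strict = TRUE) {
  nt <- length(trials)
  if (strict && nt != 40L)
    stopf("DEAP layout requires 40 trials per subject, got %d", nt)
  ns <- ncol(trials[[1]]$signal)
  data <- array(0, dim = c(nt, 40L, ns))
  labels <- matrix(NA_real_, nt, 4L)
  for (t in seq_len(nt)) {
    if (ncol(trials[[t]]$signal) != ns)
      stopf("trials have inconsistent sample counts")
    data[t, 1:32, ] <- trials[[t]]$signal
    labels[t, ] <- trials[[t]]$ratings
  }
  obj <- list(data = data, labels = labels,
              subject_id = trials[[1]]$subject_id,
              sampling_rate_hz = trials[[1]]$sampling_rate_hz)
  ok <- tryCatch({ saveRDS(obj, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stopf("failed to write subject file %s: %s", path,
          conditionMessage(ok))
  invisible(path)
}
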