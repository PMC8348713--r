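# Independent brute-force oracles and small fixtures, kept deliberately
# naive (plain loops, textbook formulas) so they share no code with the
# implementation they check.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_mean_d1 <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + (x[i + 1] - x[i])
  s / (length(x) - 1)
}

oracle_mean_d2 <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 2)) s <- s + (x[i + 2] - x[i])
  s / (length(x) - 2)
}

oracle_var <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}

oracle_std <- function(x) sqrt(oracle_var(x))

oracle_de <- function(x) 0.5 * log(2 * pi * exp(1) * oracle_var(x))

# naive direct convolution (same padding) on a channels-first matrix
oracle_conv <- function(x, H, W, N, k, Wm, b) {
  C <- nrow(x)
  cout <- nrow(Wm)
  p <- (k - 1) / 2
  xa <- array(x, c(C, H, W, N))
  y <- array(0, c(cout, H, W, N))
  for (n in seq_len(N)) for (w in seq_len(W)) for (h in seq_len(H)) {
    patch <- numeric(C * k * k)
    for (kw in seq_len(k)) for (kh in seq_len(k)) {
      hh <- h + kh - 1 - p
      ww <- w + kw - 1 - p
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        patch[((kw - 1) * k + (kh - 1)) * C + seq_len(C)] <- xa[, hh, ww, n]
    }
    y[, h, w, n] <- Wm %*% patch + b
  }
  matrix(y, cout)
}

# a trial whose channels are pure sinusoids (plus tiny noise to avoid
# degenerate constant segments), for pipeline plumbing tests
make_sine_trial <- function(freq = 10, fs = 128, duration = 63,
                            subject = 1, trial = 1, rating = 7, seed = 99) {
  set.seed(seed)
  tt <- seq_len(duration * fs) / fs
  sig <- matrix(rep(sin(2 * pi * freq * tt), each = 32), 32, byrow = FALSE) +
    matrix(rnorm(32 * length(tt), sd = 1e-3), 32)
  rownames(sig) <- deap_channels()
  trial_record(subject, trial, sig,
               c(valence = rating, arousal = rating,
                 dominance = 5, liking = 5), fs)
}

rms <- function(x) sqrt(mean(x^2))

# small synthetic dataset shared by the heavier pipeline tests
small_synth_trials <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synth_config(n_subjects = 1,
                                              n_trials_per_subject = 6,
                                              trial_duration_s = 13,
                                              effect_size = 1.5, seed = 5))
    cache
  }
})
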