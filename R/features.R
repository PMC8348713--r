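#' Time-domain feature names, in depth order
#'
#' The six per-segment features: differential entropy, mean, mean first
#' difference, mean second difference, standard deviation, variance. The
#' order fixes the depth (third) dimension of assembled sample tensors.
#'
#' @return Character vector of length 6.
#' @export
feature_names <- function() {
  c("de", "mean", "mean_d1", "mean_d2", "std", "var")
}

#' Differential entropy of a segment
#'
#' Differential entropy is the continuous-variable entropy
#' \eqn{-\int p(x)\log p(x)\,dx}. The default estimator models the segment as
#' Gaussian — the standard choice for band-limited EEG — for which the
#' integral has the closed form \eqn{\frac12 \ln(2\pi e \sigma^2)} (in
#' nats), with \eqn{\sigma^2} the biased (1/n) sample variance. A histogram
#' plug-in estimator (\eqn{-\sum_i p_i \ln p_i + \ln \Delta} over
#' equal-width bins \eqn{\Delta}, Sturges' count) is available for
#' comparison. A constant segment has no finite differential entropy; it is
#' floored at the value for the smallest representable positive variance,
#' with a warning.
#'
#' @param x Numeric vector, length >= 2.
#' @param method `"gaussian"` (default, closed form) or `"histogram"`
#'   (plug-in).
#' @return Differential entropy in nats.
#' @export
#' @examples
#' differential_entropy(c(1, -1, 1, -1))  # 0.5 * log(2*pi*e) = 1.4189
differential_entropy <- function(x, method = c("gaussian", "histogram")) {
  method <- match.arg(method)
  if (length(x) < 2) stopf("segment must have length >= 2")
  v <- biased_var(x)
  if (v <= 0) {
    warning("zero-variance segment: differential entropy floored")
    return(0.5 * log(2 * pi * exp(1) * .Machine$double.xmin))
  }
  if (method == "gaussian") return(0.5 * log(2 * pi * exp(1) * v))
  nbin <- max(2L, ceiling(log2(length(x))) + 1L)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbin + 1L),
            plot = FALSE)
  p <- h$counts / length(x)
  p <- p[p > 0]
  delta <- diff(h$breaks[1:2])
  -sum(p * log(p)) + log(delta)
}

biased_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}

#' Elementary time-domain features
#'
#' Literal implementations of the per-segment statistics: mean, mean of the
#' first and second (signed) differences, biased variance and its square
#' root. `seg_mean_d1(x) = mean(x[i+1] - x[i])` over `n - 1` terms and
#' `seg_mean_d2(x) = mean(x[i+2] - x[i])` over `n - 2` terms; the signed sums
#' telescope, which is kept as specified (an `absolute` flag gives the
#' rectified variant common elsewhere in the first-difference literature).
#'
#' @param x Numeric vector, length >= 3.
#' @param absolute Use absolute differences instead of signed (default
#'   `FALSE`).
#' @return A scalar.
#' @name segment_features
#' @export
seg_mean <- function(x) {
  check_seg(x)
  sum(x) / length(x)
}

#' @rdname segment_features
#' @export
seg_mean_d1 <- function(x, absolute = FALSE) {
  check_seg(x)
  d <- diff(x)
  if (absolute) d <- abs(d)
  sum(d) / (length(x) - 1)
}

#' @rdname segment_features
#' @export
seg_mean_d2 <- function(x, absolute = FALSE) {
  check_seg(x)
  d <- diff(x, lag = 2)
  if (absolute) d <- abs(d)
  sum(d) / (length(x) - 2)
}

#' @rdname segment_features
#' @export
seg_var <- function(x) {
  check_seg(x)
  biased_var(x)
}

#' @rdname segment_features
#' @export
seg_std <- function(x) sqrt(seg_var(x))

check_seg <- function(x) {
  if (length(x) < 3) stopf("segment must have length >= 3")
  invisible(x)
}

# all six features of one segment vector, in feature_names() order
segment_feature_vector <- function(x, absolute = FALSE) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  de <- if (v > 0) 0.5 * log(2 * pi * exp(1) * v) else {
    warning("zero-variance segment: differential entropy floored")
    0.5 * log(2 * pi * exp(1) * .Machine$double.xmin)
  }
  d1 <- if (absolute) sum(abs(diff(x))) else x[n] - x[1]
  d2 <- if (absolute) sum(abs(diff(x, lag = 2))) else
    x[n] + x[n - 1] - x[2] - x[1]
  c(de = de, mean = m, mean_d1 = d1 / (n - 1), mean_d2 = d2 / (n - 2),
    std = sqrt(v), var = v)
}

#' Extract all features for one trial
#'
#' Computes the six time-domain features for every (segment, channel, band)
#' of one trial. `band_segments` is a named list (one entry per band, or
#' `raw`) whose elements are lists of channels x samples segment matrices as
#' returned by [split_trial()].
#'
#' @param band_segments Named list: band -> list of segment matrices.
#' @param absolute Use absolute first/second differences (default `FALSE`).
#' @return Numeric 4-d array `[segment, channel, band, feature]` with
#'   dimnames.
#' @export
extract_features <- function(band_segments, absolute = FALSE) {
  bands <- names(band_segments)
  if (is.null(bands)) stopf("band_segments must be a named list")
  n_seg <- length(band_segments[[1]])
  n_ch <- nrow(band_segments[[1]][[1]])
  out <- array(NA_real_,
               dim = c(n_seg, n_ch, length(bands), 6L),
               dimnames = list(NULL,
                               rownames(band_segments[[1]][[1]]),
                               bands, feature_names()))
  for (b in seq_along(bands)) {
    segs <- band_segments[[b]]
    if (length(segs) != n_seg)
      stopf("band '%s' has %d segments, expected %d", bands[b],
            length(segs), n_seg)
    for (s in seq_len(n_seg))
      out[s, , b, ] <- segment_feature_matrix(segs[[s]], absolute = absolute)
  }
  out
}

# all six features for every row of a channels x samples segment matrix;
# row-vectorized twin of segment_feature_vector (equality is tested)
segment_feature_matrix <- function(seg, absolute = FALSE) {
  n <- ncol(seg)
  m <- rowMeans(seg)
  cen <- seg - m
  v <- rowMeans(cen * cen)
  bad <- v <= 0
  if (any(bad)) {
    warning("zero-variance segment: differential entropy floored")
    v[bad] <- .Machine$double.xmin
  }
  de <- 0.5 * log(2 * pi * exp(1) * v)
  if (absolute) {
    d1 <- rowSums(abs(seg[, -1, drop = FALSE] - seg[, -n, drop = FALSE]))
    d2 <- rowSums(abs(seg[, -(1:2), drop = FALSE] -
                        seg[, -((n - 1):n), drop = FALSE]))
  } else {
    d1 <- seg[, n] - seg[, 1]
    d2 <- seg[, n] + seg[, n - 1] - seg[, 2] - seg[, 1]
  }
  cbind(de = de, mean = m, mean_d1 = d1 / (n - 1), mean_d2 = d2 / (n - 2),
        std = sqrt(v), var = v)
}

#' Min-max normalize one trial's features to \[0, 1\]
#'
#' Rescales `f <- (f - f_min) / (f_max - f_min)` where the minimum and
#' maximum are taken within the trial. The default grouping pools channels
#' and segments separately for each (band, feature) pair, so quantities with
#' different physical units are never mixed while the spatial topography of
#' each feature is preserved. A group with `f_max == f_min` is set to 0 with
#' a warning.
#'
#' @param features 4-d `[segment, channel, band, feature]` array from
#'   [extract_features()] (one trial).
#' @param grouping `"band_feature"` (default), `"trial"` (one global group),
#'   or `"channel_band_feature"`.
#' @return Array of the same shape with all values in \[0, 1\].
#' @export
normalize_trial <- function(features,
                            grouping = c("band_feature", "trial",
                                         "channel_band_feature")) {
  grouping <- match.arg(grouping)
  d <- dim(features)
  out <- features
  scale_group <- function(vals) {
    fmin <- min(vals); fmax <- max(vals)
    if (fmax == fmin) {
      warning("constant feature group: normalized to 0")
      vals[] <- 0
    } else {
      vals <- (vals - fmin) / (fmax - fmin)
    }
    vals
  }
  if (grouping == "trial") {
    out[] <- scale_group(as.vector(features))
  } else if (grouping == "band_feature") {
    for (b in seq_len(d[3])) for (f in seq_len(d[4]))
      out[, , b, f] <- scale_group(features[, , b, f])
  } else {
    for (ch in seq_len(d[2])) for (b in seq_len(d[3])) for (f in seq_len(d[4]))
      out[, ch, b, f] <- scale_group(features[, ch, b, f])
  }
  out
}
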