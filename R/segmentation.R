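#' Segmentation specification
#'
#' Describes how a recorded trial is cut: discard the pre-stimulus baseline,
#' optionally shift the start, then cut the active period into `n_segments`
#' equal, contiguous, non-overlapping windows. Defaults reproduce the
#' standard protocol: 3 s baseline, 60 s active, 10 segments of 6 s.
#'
#' @param baseline_s Pre-stimulus baseline to discard (s, default 3).
#' @param active_s Active period to segment (s, default 60).
#' @param n_segments Number of equal segments (default 10).
#' @param start_offset_s Additional start shift after the baseline (s,
#'   default 0) - the axis of the start-shift ablation.
#' @param truncate_tail If `TRUE`, segments overrunning the recording are
#'   dropped instead of raising an error (needed for nonzero shifts inside a
#'   fixed-length recording).
#' @return A `segment_spec` list.
#' @export
segment_spec <- function(baseline_s = 3, active_s = 60, n_segments = 10,
                         start_offset_s = 0, truncate_tail = FALSE) {
  if (n_segments < 1) stopf("n_segments must be >= 1")
  if (active_s <= 0) stopf("active_s must be positive")
  if (start_offset_s < 0) stopf("start_offset_s must be >= 0")
  structure(list(baseline_s = baseline_s, active_s = active_s,
                 n_segments = as.integer(n_segments),
                 start_offset_s = start_offset_s,
                 truncate_tail = isTRUE(truncate_tail)),
            class = "segment_spec")
}

#' Cut a trial into equal non-overlapping segments
#'
#' The baseline (and any start offset) is discarded, then `n_segments`
#' contiguous windows of `active_s / n_segments` seconds are extracted.
#' Sample boundaries are computed with round-half-even on `fs * seconds`;
#' all default settings yield exact integers. Concatenating the returned
#' segments reproduces the corresponding slice of the input bit-exactly.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param spec A [segment_spec()].
#' @return List of channels x samples matrices (length `n_segments`, or fewer
#'   when `truncate_tail` drops overrunning segments).
#' @export
#' @examples
#' x <- matrix(rnorm(2 * 63 * 128), 2)
#' segs <- split_trial(x, 128, segment_spec())
#' length(segs); ncol(segs[[1]])  # 10 segments of 768 samples
split_trial <- function(signal, fs, spec = segment_spec()) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  n_avail <- ncol(signal)
  seg_len <- as.integer(round(fs * spec$active_s / spec$n_segments))
  if (seg_len < 1) stopf("segment length is below one sample")
  start <- as.integer(round(fs * (spec$baseline_s + spec$start_offset_s)))
  need <- start + spec$n_segments * seg_len
  n_keep <- spec$n_segments
  if (need > n_avail) {
    if (!spec$truncate_tail)
      stopf("segmentation overflow: need %d samples, recording has %d (short by %d)",
            need, n_avail, need - n_avail)
    n_keep <- (n_avail - start) %/% seg_len
    if (n_keep < 1)
      stopf("segmentation overflow: no full segment fits after offset (short by %d samples)",
            seg_len - (n_avail - start))
  }
  lapply(seq_len(n_keep), function(i)
    signal[, start + (i - 1L) * seg_len + seq_len(seg_len), drop = FALSE])
}
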