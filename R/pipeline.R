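#' Build model-ready sample tensors from trials
#'
#' Runs the full feature pipeline on a list of trials: band decomposition
#' (Butterworth filter bank; skipped for the `"raw"` arm), baseline removal
#' and segmentation, time-domain feature extraction, per-trial min-max
#' normalization, topographic mapping and band tiling. Trials are processed
#' one at a time so memory stays proportional to one trial plus the output
#' tensors.
#'
#' @param trials List of [trial_record()]s.
#' @param bands Character vector of band names (subset of theta, alpha, beta,
#'   gamma) or `"raw"` for the unfiltered arm. Tensor width follows the band
#'   count: 4 bands give 18x18, 2 give 9x18, 1 or raw give 9x9.
#' @param spec A [segment_spec()].
#' @param task Label task, see [label_for_task()].
#' @param threshold Rating split point (default 5).
#' @param layout Electrode layout.
#' @param order Filter design order (default 30).
#' @param zero_phase Zero-phase filtering (default TRUE).
#' @param grouping Normalization grouping, see [normalize_trial()].
#' @param absolute Absolute first/second differences (default FALSE).
#' @return List: `x` array `(H, W, 6, N)`, `y` 0-based integer labels,
#'   `meta` data.frame (subject, trial, segment), `n_classes`.
#' @export
#' @examples
#' \donttest{
#' cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 4,
#'                     trial_duration_s = 13, seed = 7)
#' trials <- generate_dataset(cfg)
#' ds <- prepare_samples(trials, bands = "raw",
#'                       spec = segment_spec(active_s = 10, n_segments = 5))
#' dim(ds$x)  # 9 9 6 20
#' }
prepare_samples <- function(trials, bands = c("theta", "alpha", "beta",
                                              "gamma"),
                            spec = segment_spec(),
                            task = "arousal_binary", threshold = 5,
                            layout = default_layout(), order = 30,
                            zero_phase = TRUE,
                            grouping = "band_feature", absolute = FALSE) {
  raw <- identical(bands, "raw")
  if (!raw && !all(bands %in% names(band_definitions())))
    stopf("unknown bands: %s",
          paste(setdiff(bands, names(band_definitions())), collapse = ", "))
  filters <- if (!raw) {
    defs <- band_definitions(order)[bands]
    lapply(defs, function(b) design_bandpass(b$low_hz, b$high_hz,
                                             trials[[1]]$sampling_rate_hz,
                                             order))
  }
  xs <- vector("list", length(trials))
  ys <- vector("list", length(trials))
  meta <- vector("list", length(trials))
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    fs <- tr$sampling_rate_hz
    band_signals <- if (raw) list(raw = tr$signal) else
      lapply(filters, function(f)
        t(sos_filter_apply(f, t(tr$signal), zero_phase = zero_phase)))
    band_segments <- lapply(band_signals, function(sig) {
      rownames(sig) <- rownames(tr$signal) %||% deap_channels()
      split_trial(sig, fs, spec)
    })
    feats <- extract_features(band_segments, absolute = absolute)
    feats <- normalize_trial(feats, grouping = grouping)
    n_seg <- dim(feats)[1]
    xs[[ti]] <- assemble_trial_tensors(feats, layout)
    ys[[ti]] <- rep(label_for_task(tr$ratings, task, threshold), n_seg)
    meta[[ti]] <- data.frame(subject = tr$subject_id, trial = tr$trial_id,
                             segment = seq_len(n_seg))
  }
  hwd <- dim(xs[[1]])[1:3]
  x <- array(unlist(xs, use.names = FALSE),
             c(hwd, sum(vapply(xs, function(a) dim(a)[4], integer(1)))))
  list(x = x, y = unlist(ys), meta = do.call(rbind, meta),
       n_classes = n_classes_for_task(task))
}

# vectorized twin of calling assemble_sample() per segment (equality is
# tested); returns (H, W, n_features, n_segments)
assemble_trial_tensors <- function(feats, layout = default_layout(),
                                   feature_order = feature_names()) {
  d <- dim(feats)  # segment, channel, band, feature
  bands <- dimnames(feats)[[3]]
  nb <- length(bands)
  offs <- switch(as.character(nb),
                 "1" = list(c(0L, 0L)),
                 "2" = list(c(0L, 0L), c(0L, 9L)),
                 "4" = list(c(0L, 0L), c(0L, 9L), c(9L, 0L), c(9L, 9L)),
                 stopf("tiling defined for 1, 2 or 4 bands, got %d", nb))
  H <- if (nb == 4L) 18L else 9L
  W <- if (nb == 1L) 9L else 18L
  pos <- layout_positions(layout, dimnames(feats)[[2]] %||% deap_channels())
  idx <- vapply(seq_len(nb), function(b)
    (pos[, "row"] + offs[[b]][1]) + (pos[, "col"] + offs[[b]][2]) * H + 1L,
    integer(nrow(pos)))
  feats <- feats[, , , feature_order, drop = FALSE]
  if (min(feats) < 0 || max(feats) > 1)
    stopf("features must be normalized to [0, 1]")
  out <- array(0, c(H, W, d[4], d[1]))
  plane <- numeric(H * W)
  for (s in seq_len(d[1])) for (f in seq_len(d[4])) {
    plane[as.vector(idx)] <- as.vector(feats[s, , , f])
    out[, , f, s] <- plane
  }
  dimnames(out) <- list(NULL, NULL, feature_order, NULL)
  out
}

#' Ablation harness over bands, kernel sets or start shifts
#'
#' Re-runs cross-validation along one experimental axis: `bands` (which
#' frequency bands feed the tensor), `kernels` (which kernel-size sets build
#' the blocks) or `shift` (segmentation start offsets in seconds, with
#' trailing segments that overrun the recording dropped).
#'
#' @param axis `"bands"`, `"kernels"` or `"shift"`.
#' @param grid List of grid points: character vectors of band names, integer
#'   vectors of kernel sizes, or numeric offsets.
#' @param trials List of [trial_record()]s.
#' @param mcfg Base [model_config()] (input shape is re-derived per point).
#' @param tcfg A [train_config()].
#' @param task Label task.
#' @param ... Passed to [prepare_samples()].
#' @return Data frame: one row per grid point with the mean CV accuracy and
#'   fold standard deviation. Invalid grid points are skipped with a warning
#'   and an `NA` row.
#' @export
run_ablation <- function(axis = c("bands", "kernels", "shift"), grid, trials,
                         mcfg, tcfg, task = "arousal_binary", ...) {
  axis <- match.arg(axis)
  rows <- lapply(grid, function(g) {
    res <- tryCatch({
      if (axis == "bands") {
        ds <- prepare_samples(trials, bands = g, task = task, ...)
        cfg <- model_config(mcfg$kernel_sizes, mcfg$block_channels,
                            ds$n_classes, dim(ds$x)[1:3])
      } else if (axis == "kernels") {
        ds <- prepare_samples(trials, task = task, ...)
        cfg <- model_config(g, mcfg$block_channels, ds$n_classes,
                            dim(ds$x)[1:3])
      } else {
        ds <- prepare_samples(trials,
                              spec = segment_spec(start_offset_s = g,
                                                  truncate_tail = TRUE),
                              task = task, ...)
        cfg <- model_config(mcfg$kernel_sizes, mcfg$block_channels,
                            ds$n_classes, dim(ds$x)[1:3])
      }
      cv <- run_cross_validation(ds$x, ds$y, cfg, tcfg)
      c(mean = cv$mean_accuracy, sd = sd(cv$fold_accuracies),
        n = length(cv$fold_accuracies))
    }, error = function(e) {
      warning(sprintf("grid point [%s] skipped: %s",
                      paste(g, collapse = ","), conditionMessage(e)))
      c(mean = NA_real_, sd = NA_real_, n = NA_real_)
    })
    data.frame(point = paste(g, collapse = "+"),
               mean_accuracy = res[["mean"]], fold_sd = res[["sd"]],
               n_folds = res[["n"]])
  })
  out <- do.call(rbind, rows)
  out$axis <- axis
  out
}
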