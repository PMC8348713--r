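#' Map 32 channel values onto the 9x9 scalp grid
#'
#' Places each channel's value at its electrode's (row, col) cell; the 49
#' cells with no electrode are exactly zero.
#'
#' @param channel_values Numeric vector of 32 values. If named, names are
#'   matched against the layout; if unnamed, [deap_channels()] order is
#'   assumed.
#' @param layout An `electrode_layout` (default [default_layout()]).
#' @return 9x9 numeric matrix.
#' @export
#' @examples
#' g <- map_to_grid(setNames(rep(1, 32), deap_channels()))
#' sum(g != 0)  # 32
map_to_grid <- function(channel_values, layout = default_layout()) {
  if (is.null(names(channel_values))) {
    if (length(channel_values) != 32L)
      stopf("expected 32 channel values, got %d", length(channel_values))
    names(channel_values) <- deap_channels()
  }
  missing <- setdiff(layout$name, names(channel_values))
  extra <- setdiff(names(channel_values), layout$name)
  if (length(missing) || length(extra))
    stopf("channel mismatch; missing: [%s], extra: [%s]",
          paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  grid <- matrix(0, 9L, 9L)
  pos <- layout_positions(layout, names(channel_values))
  grid[cbind(pos[, "row"] + 1L, pos[, "col"] + 1L)] <- channel_values
  grid
}

# inverse of map_to_grid: read the 32 layout cells back into a named vector
grid_to_channels <- function(grid, layout = default_layout()) {
  pos <- layout_positions(layout, layout$name)
  setNames(grid[cbind(pos[, "row"] + 1L, pos[, "col"] + 1L)], layout$name)
}

#' Tile per-band grids into one matrix (early fusion)
#'
#' Combines the per-band 9x9 grids into a single 2D matrix so the classifier
#' can learn cross-band structure: four bands tile 2x2 into 18x18 (row-major
#' in `order`: first two bands on top, last two below), two bands tile 1x2
#' into 9x18, one band passes through.
#'
#' @param band_grids Named list of 9x9 matrices.
#' @param order Band names in tiling order (default: the list's own order).
#' @return The tiled matrix.
#' @export
tile_bands <- function(band_grids, order = names(band_grids)) {
  if (!setequal(order, names(band_grids)) ||
      length(order) != length(band_grids))
    stopf("order must cover exactly the provided bands")
  grids <- band_grids[order]
  bad <- !vapply(grids, function(g) identical(dim(g), c(9L, 9L)), logical(1))
  if (any(bad))
    stopf("all band grids must be 9x9; offending: %s",
          paste(order[bad], collapse = ", "))
  n <- length(grids)
  if (n == 1L) grids[[1]]
  else if (n == 2L) cbind(grids[[1]], grids[[2]])
  else if (n == 4L) rbind(cbind(grids[[1]], grids[[2]]),
                          cbind(grids[[3]], grids[[4]]))
  else stopf("tiling defined for 1, 2 or 4 bands, got %d", n)
}

#' Assemble one segment's features into a sample tensor
#'
#' Builds the model input for one segment: per feature type, each band's 32
#' channel values are mapped onto the 9x9 scalp grid and the band grids are
#' tiled into one matrix; the six feature matrices are stacked along the
#' third (depth) dimension. Four bands and six features give an 18x18x6
#' tensor; the raw arm gives 9x9x6.
#'
#' @param features Numeric `[channel, band, feature]` slice for one segment
#'   (e.g. `extract_features(...)[s, , , ]`), normalized to \[0, 1\].
#' @param layout An `electrode_layout`.
#' @param band_order Band tiling order (default: theta, alpha top; beta,
#'   gamma bottom, i.e. the array's band order).
#' @param feature_order Depth order (default [feature_names()]).
#' @return Numeric array height x width x depth, with a `label`-free
#'   structure; labels travel with the dataset (see [prepare_samples()]).
#' @export
assemble_sample <- function(features, layout = default_layout(),
                            band_order = dimnames(features)[[2]],
                            feature_order = feature_names()) {
  if (length(dim(features)) != 3L)
    stopf("features must be a [channel, band, feature] array")
  if (min(features) < 0 || max(features) > 1)
    stopf("features must be normalized to [0, 1] (got range [%g, %g])",
          min(features), max(features))
  ch_names <- dimnames(features)[[1]] %||% deap_channels()
  slices <- lapply(feature_order, function(f) {
    grids <- lapply(setNames(band_order, band_order), function(b)
      map_to_grid(setNames(features[, b, f], ch_names), layout))
    tile_bands(grids, band_order)
  })
  array(unlist(slices, use.names = FALSE),
        dim = c(dim(slices[[1]]), length(slices)),
        dimnames = list(NULL, NULL, feature_order))
}

#' Pearson correlation of every channel against a reference channel
#'
#' The channel-connectivity view behind the multi-scale design: adjacent
#' electrodes correlate strongly while remote pairs may correlate positively,
#' negatively or not at all.
#'
#' @param trial_signal Numeric matrix, channels x samples (rownames =
#'   channel names).
#' @param reference_channel Channel name or row index.
#' @return Named vector of 32 Pearson r in \[-1, 1\]; the reference maps
#'   to 1. Constant channels yield 0 with a warning.
#' @export
pearson_correlation_map <- function(trial_signal, reference_channel) {
  if (ncol(trial_signal) < 2) stopf("need at least 2 time samples")
  if (is.character(reference_channel)) {
    idx <- match(reference_channel, rownames(trial_signal))
    if (is.na(idx)) stopf("unknown reference channel %s", reference_channel)
  } else idx <- reference_channel
  sds <- apply(trial_signal, 1, sd)
  r <- rep(0, nrow(trial_signal))
  names(r) <- rownames(trial_signal)
  if (any(sds == 0)) warning("constant channel(s): correlation reported as 0")
  ok <- sds > 0
  if (sds[idx] > 0)
    r[ok] <- as.vector(cor(trial_signal[idx, ], t(trial_signal[ok, ,
                                                               drop = FALSE])))
  r[idx] <- 1
  r
}
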