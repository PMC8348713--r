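#' DEAP EEG channel names in file order
#'
#' The 32 EEG channel names of the DEAP preprocessed release, in the native
#' (Geneva) order in which they appear in the per-subject files. Names follow
#' the international 10-20 convention: odd suffix = left hemisphere, even =
#' right, `z` = midline.
#'
#' @return Character vector of length 32.
#' @export
#' @examples
#' deap_channels()[1:4]
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Read an electrode layout file
#'
#' An electrode layout places each channel at a (row, col) cell of the 9x9
#' scalp grid used for topographic feature mapping. The file format is plain
#' text, one electrode per line: `NAME row col` with 0-based indices.
#'
#' @param path Path to a layout file.
#' @return An `electrode_layout`: a data.frame with columns `name`, `row`,
#'   `col` (0-based grid indices).
#' @seealso [default_layout()]
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stopf("layout file not found: %s", path)
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("name", "row", "col"),
                          stringsAsFactors = FALSE)
  as_electrode_layout(df)
}

as_electrode_layout <- function(df) {
  df$name <- as.character(df$name)
  df$row <- as.integer(df$row)
  df$col <- as.integer(df$col)
  validate_layout(df)
  class(df) <- c("electrode_layout", "data.frame")
  df
}

validate_layout <- function(df) {
  if (nrow(df) != 32L)
    stopf("layout must have exactly 32 electrodes, got %d", nrow(df))
  if (anyDuplicated(df$name))
    stopf("duplicate electrode names in layout")
  if (anyDuplicated(df[c("row", "col")]))
    stopf("two electrodes share one grid cell")
  if (any(df$row < 0 | df$row > 8 | df$col < 0 | df$col > 8))
    stopf("grid positions must lie in 0..8")
  # left/right homologous pairs must mirror about the midline column 4
  base <- sub("[0-9]+$", "", df$name)
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", df$name)))
  for (i in which(!is.na(num) & num %% 2L == 1L)) {
    partner <- paste0(base[i], num[i] + 1L)
    j <- match(partner, df$name)
    if (!is.na(j) && (df$row[i] != df$row[j] || df$col[i] + df$col[j] != 8L))
      stopf("homologous pair %s/%s does not mirror about column 4",
            df$name[i], partner)
  }
  invisible(df)
}

#' Default 9x9 scalp layout for the 32 DEAP electrodes
#'
#' Standard 10-20 topographic placement of DEAP's 32 channels on a 9x9 grid:
#' midline (`z`) electrodes at column 4, left (odd) electrodes at columns
#' < 4, right (even) at columns > 4. Loaded from the plain-text layout file
#' shipped with the package so an alternative convention is a one-file edit.
#'
#' @return An `electrode_layout` data.frame (32 rows).
#' @export
#' @examples
#' lay <- default_layout()
#' subset(lay, name %in% c("Fz", "Cz", "Pz"))
default_layout <- function() {
  path <- system.file("extdata", "deap_9x9_layout.txt", package = "msceeg")
  read_layout(path)
}

# 0-based (row, col) for a channel name, as a 2-column matrix aligned to `names`
layout_positions <- function(layout, names) {
  idx <- match(names, layout$name)
  if (anyNA(idx))
    stopf("channels missing from layout: %s",
          paste(names[is.na(idx)], collapse = ", "))
  cbind(row = layout$row[idx], col = layout$col[idx])
}

# Chebyshev grid distance between all pairs of layout electrodes
layout_grid_distance <- function(layout) {
  dr <- abs(outer(layout$row, layout$row, "-"))
  dc <- abs(outer(layout$col, layout$col, "-"))
  d <- pmax(dr, dc)
  dimnames(d) <- list(layout$name, layout$name)
  d
}
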