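#' Electrode montages and the 8x9 topographic grid
#'
#' Channels are laid out on an 8-row by 9-column scalp grid (row 0 frontal,
#' column 0 left hemisphere). The shipped 62-channel cap fills 62 of the 72
#' cells; a 32-channel cap is also provided. The assignment is a documented
#' package default and can be replaced by any injective channel -> (row, col)
#' table.
#'
#' @param name Montage name: `"cap62"` or `"cap32"`.
#' @return A `montage` object: data.frame with columns `channel`, `row`, `col`
#'   (0-based grid coordinates).
#' @export
default_montage <- function(name = "cap62") {
  rows <- switch(
    name,
    cap62 = list(
      list(r = 0L, ch = c("AF3", "FP1", "FPZ", "FP2", "AF4"), col = c(2L, 3L, 4L, 5L, 6L)),
      list(r = 1L, ch = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8"), col = 0:8),
      list(r = 2L, ch = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8"), col = 0:8),
      list(r = 3L, ch = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8"), col = 0:8),
      list(r = 4L, ch = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8"), col = 0:8),
      list(r = 5L, ch = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8"), col = 0:8),
      list(r = 6L, ch = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8"), col = 1:7),
      list(r = 7L, ch = c("CB1", "O1", "OZ", "O2", "CB2"), col = 2:6)),
    cap32 = list(
      list(r = 0L, ch = c("AF3", "FP1", "FP2", "AF4"), col = c(2L, 3L, 5L, 6L)),
      list(r = 1L, ch = c("F7", "F3", "FZ", "F4", "F8"), col = c(0L, 2L, 4L, 6L, 8L)),
      list(r = 2L, ch = c("FC5", "FC1", "FC2", "FC6"), col = c(1L, 3L, 5L, 7L)),
      list(r = 3L, ch = c("T7", "C3", "CZ", "C4", "T8"), col = c(0L, 2L, 4L, 6L, 8L)),
      list(r = 4L, ch = c("CP5", "CP1", "CP2", "CP6"), col = c(1L, 3L, 5L, 7L)),
      list(r = 5L, ch = c("P7", "P3", "PZ", "P4", "P8"), col = c(0L, 2L, 4L, 6L, 8L)),
      list(r = 6L, ch = c("PO3", "PO4"), col = c(3L, 5L)),
      list(r = 7L, ch = c("O1", "OZ", "O2"), col = 3:5)),
    stop_invalid("unknown montage `%s`", name))
  df <- do.call(rbind, lapply(rows, function(x)
    data.frame(channel = x$ch, row = x$r, col = x$col, stringsAsFactors = FALSE)))
  structure(df, class = c("montage", "data.frame"), montage_name = name)
}

#' Build an electrode-to-grid map
#'
#' @param montage A `montage` object (or data.frame with `channel`, `row`,
#'   `col`), rows/cols 0-based within an `nrow` x `ncol` grid.
#' @param nrow,ncol Grid dimensions (default 8 x 9).
#' @return A `grid_map` object used by [map_to_grid()] and [assemble_4d()].
#' @export
grid_map <- function(montage, nrow = 8L, ncol = 9L) {
  df <- as.data.frame(montage)
  stopifnot(all(c("channel", "row", "col") %in% names(df)))
  if (any(df$row < 0 | df$row >= nrow | df$col < 0 | df$col >= ncol))
    stop_invalid("grid coordinates out of range for a %dx%d grid", nrow, ncol)
  cell <- df$row + nrow * df$col  # 0-based column-major cell id
  if (anyDuplicated(cell))
    stop_invalid("grid map is not injective: two channels share a cell")
  if (anyDuplicated(df$channel))
    stop_invalid("duplicated channel name in montage")
  structure(list(channel = df$channel, row = df$row, col = df$col,
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 index = 1L + df$row + nrow * df$col),
            class = "grid_map")
}

# 0/1 mask of cells that carry an electrode, as an nrow x ncol matrix.
grid_mask <- function(gm) {
  m <- matrix(0, gm$nrow, gm$ncol)
  m[gm$index] <- 1
  m
}

# Scalp region per channel from its grid row: rows 0-2 frontal, 3-5 central,
# 6-7 parietal-occipital. Used by the synthetic generator's class signatures.
channel_regions <- function(gm) {
  cut(gm$row, breaks = c(-1, 2, 5, 8),
      labels = c("frontal", "central", "posterior"))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage `%s`: %d channels on an 8x9 grid>\n",
              attr(x, "montage_name"), nrow(x)))
  invisible(x)
}
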