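#' Planar multielectrode array layout
#'
#' Builds the standard 60-electrode MEA layout: an 8 x 8 grid with 200 um
#' pitch and the four corner sites absent.  All electrodes lie on the plane
#' z = 0 and are treated as ideal points.  Coordinates are centred on the
#' grid so that electrode (row 4, col 4) sits near the array centre.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch Electrode spacing in metres.
#' @param drop_corners Remove the four corner sites (the standard layout).
#' @return Object of class `mea_array`: a data frame with columns `label`,
#'   `row`, `col`, `x`, `y`, `z`.
#' @export
mea_array <- function(n_rows = 8L, n_cols = 8L, pitch = 200e-6,
                      drop_corners = TRUE) {
  stopifnot(n_rows >= 2L, n_cols >= 2L, pitch > 0)
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  if (drop_corners) {
    corner <- (g$row %in% c(1L, n_rows)) & (g$col %in% c(1L, n_cols))
    g <- g[!corner, , drop = FALSE]
  }
  g$label <- sprintf("E%d%d", g$col, g$row)
  g$x <- (g$col - (n_cols + 1) / 2) * pitch
  g$y <- (g$row - (n_rows + 1) / 2) * pitch
  g$z <- 0
  rownames(g) <- NULL
  structure(g[, c("label", "row", "col", "x", "y", "z")],
            class = c("mea_array", "data.frame"))
}

#' @export
print.mea_array <- function(x, ...) {
  cat("MEA array:", nrow(x), "electrodes,",
      max(x$row), "x", max(x$col), "grid\n")
  invisible(x)
}

#' Electrode positions as a matrix
#'
#' @param array An [mea_array()].
#' @return n x 3 matrix of positions in metres, rownames = labels.
#' @export
electrode_positions <- function(array) {
  stopifnot(inherits(array, "mea_array"))
  m <- as.matrix(array[, c("x", "y", "z")])
  rownames(m) <- array$label
  m
}

#' Immediate grid neighbours of an electrode
#'
#' Neighbours are the (up to eight) sites whose row and column indices both
#' differ by at most one.
#'
#' @param array An [mea_array()].
#' @param label Electrode label.
#' @return Character vector of neighbour labels.
#' @export
mea_neighbors <- function(array, label) {
  i <- match(label, array$label)
  if (is.na(i)) stop("unknown electrode label: ", label)
  sel <- abs(array$row - array$row[i]) <= 1L &
         abs(array$col - array$col[i]) <= 1L
  sel[i] <- FALSE
  array$label[sel]
}
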