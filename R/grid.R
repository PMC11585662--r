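#' Build the two-compartment electrode grid
#'
#' Describes the 8x8 microelectrode array under the microfluidic divider.
#' Rows `1 .. boundary_row - 1` lie under the midbrain-organoid (MO)
#' compartment, rows `boundary_row .. n_rows` under the striatum-organoid
#' (StrO) compartment. Electrodes are named `"R<row>C<col>"`, 1-based, with
#' row 1 at the MO edge. Positions are stored in pitch units; the y axis
#' points from MO towards StrO (increasing row), the x axis along columns.
#' Conversion to metres happens only where physical speed is computed.
#'
#' @param pitch_um centre-to-centre electrode distance in micrometres
#'   (required: plate pitch is hardware-specific, there is no safe default).
#' @param boundary_row first StrO row (1..n_rows); rows before it are MO.
#' @param n_rows,n_cols grid dimensions (default 8x8).
#' @return An `electrode_grid` with fields `n_rows`, `n_cols`, `pitch_um`,
#'   `boundary_row`, `electrodes` (character vector, row-major),
#'   `positions` (data.frame: electrode, row, col, x, y in pitch units,
#'   compartment).
#' @examples
#' g <- build_grid(pitch_um = 300, boundary_row = 5)
#' grid_distance(g, "R1C1", "R1C2")  # 1 pitch unit
#' @export
build_grid <- function(pitch_um, boundary_row, n_rows = 8L, n_cols = 8L) {
  stopifnot(length(pitch_um) == 1L, length(boundary_row) == 1L)
  if (!is.finite(pitch_um) || pitch_um <= 0)
    stop("pitch_um must be a positive number of micrometres")
  boundary_row <- as.integer(boundary_row)
  if (boundary_row < 1L || boundary_row > n_rows)
    stop(sprintf("boundary_row must be in 1..%d", n_rows))
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  positions <- data.frame(
    electrode = sprintf("R%dC%d", rows, cols),
    row = rows, col = cols,
    x = as.numeric(cols), y = as.numeric(rows),
    compartment = ifelse(rows < boundary_row, "MO", "StrO"),
    stringsAsFactors = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch_um = as.numeric(pitch_um),
                 boundary_row = boundary_row,
                 electrodes = positions$electrode,
                 positions = positions),
            class = "electrode_grid")
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf(
    "<electrode_grid %dx%d, pitch %g um, MO rows 1-%d, StrO rows %d-%d>\n",
    x$n_rows, x$n_cols, x$pitch_um, x$boundary_row - 1L, x$boundary_row,
    x$n_rows))
  invisible(x)
}

#' Electrode position in pitch units
#' @param grid an [electrode_grid].
#' @param electrode electrode id(s), e.g. `"R3C5"`.
#' @return numeric matrix with columns `x`, `y` (pitch units).
#' @export
grid_position <- function(grid, electrode) {
  stopifnot(inherits(grid, "electrode_grid"))
  i <- match(electrode, grid$positions$electrode)
  if (anyNA(i))
    stop("unknown electrode code(s): ",
         paste(electrode[is.na(i)], collapse = ", "))
  cbind(x = grid$positions$x[i], y = grid$positions$y[i])
}

#' Euclidean distance between two electrodes
#' @inheritParams grid_position
#' @param e1,e2 electrode ids.
#' @param units `"pitch"` (default) or `"m"` (metres, via `pitch_um`).
#' @export
grid_distance <- function(grid, e1, e2, units = c("pitch", "m")) {
  units <- match.arg(units)
  p1 <- grid_position(grid, e1)
  p2 <- grid_position(grid, e2)
  d <- sqrt((p1[, "x"] - p2[, "x"])^2 + (p1[, "y"] - p2[, "y"])^2)
  if (units == "m") d <- d * grid$pitch_um * 1e-6
  unname(d)
}

#' Compartment label of an electrode
#' @inheritParams grid_position
#' @return character vector of `"MO"` / `"StrO"` labels.
#' @export
grid_compartment <- function(grid, electrode) {
  stopifnot(inherits(grid, "electrode_grid"))
  i <- match(electrode, grid$positions$electrode)
  if (anyNA(i))
    stop("unknown electrode code(s): ",
         paste(electrode[is.na(i)], collapse = ", "))
  grid$positions$compartment[i]
}

#' Mirror a recording through the compartment boundary
#'
#' Remaps every electrode of row `r` to row `n_rows + 1 - r` (same column),
#' i.e. reflects the recording through the horizontal midline of the array,
#' exchanging which physical compartment each train came from. By symmetry
#' this flips the sign of the vertical directionality component and leaves
#' the lateral component unchanged; used to validate that symmetry.
#' @param recording an [mea_recording].
#' @export
mirror_recording <- function(recording) {
  stopifnot(inherits(recording, "mea_recording"))
  grid <- recording$grid
  pos <- grid$positions
  new_id <- function(e) {
    i <- match(e, pos$electrode)
    sprintf("R%dC%d", grid$n_rows + 1L - pos$row[i], pos$col[i])
  }
  trains <- recording$trains
  for (k in seq_along(trains)) {
    id <- new_id(trains[[k]]$electrode_id)
    trains[[k]]$electrode_id <- id
  }
  names(trains) <- vapply(trains, `[[`, character(1), "electrode_id")
  mea_recording(trains, grid, recording$metadata)
}
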