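#' Regular grid electrode montage
#'
#' Build a rectangular electrode montage such as the 16 x 16 ultra-high-density
#' grid (8.6 mm inter-electrode pitch) used for sensorimotor finger decoding.
#' Electrodes are ordered row-major, matching grids attached sequentially in the
#' downward direction from the origin electrode.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param pitch_mm Inter-electrode distance in millimetres.
#' @param origin_label Label of the electrode the grid is anchored at.
#'
#' @return An object of class `scbam_montage`: a list with `n_rows`, `n_cols`,
#'   `pitch_mm`, `origin_label` and `coords`, a data.frame of per-electrode
#'   `(x, y)` positions in mm (x increases to the right, y decreases downward).
#'
#' @examples
#' m <- make_grid_montage(16, 16, 8.6)
#' nrow(m$coords)  # 256 electrodes
#' @export
make_grid_montage <- function(n_rows, n_cols, pitch_mm, origin_label = "Cz") {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop_invalid("n_rows and n_cols must be positive integers")
  if (!is.numeric(pitch_mm) || pitch_mm <= 0)
    stop_invalid("pitch_mm must be > 0")
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  # expand.grid varies its first factor fastest -> row-major electrode order
  coords <- data.frame(
    electrode = seq_len(n_rows * n_cols),
    x = (grid$col - 1) * pitch_mm,
    y = -(grid$row - 1) * pitch_mm
  )
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pitch_mm = pitch_mm, origin_label = origin_label, coords = coords),
    class = "scbam_montage")
}

#' @export
print.scbam_montage <- function(x, ...) {
  cat(sprintf("<scbam_montage> %d x %d grid, %d electrodes, pitch %.3g mm (origin %s)\n",
              x$n_rows, x$n_cols, nrow(x$coords), x$pitch_mm, x$origin_label))
  invisible(x)
}

n_electrodes <- function(montage) nrow(montage$coords)
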