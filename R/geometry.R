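#' Physical layout of the tactile sensing mat
#'
#' Describes the stitched pressure grid: four 32 x 32 piezoresistive modules
#' tiled 2 x 2 into a 64 x 64 array covering (by default) 80 cm along the
#' anteroposterior (AP) axis and 60 cm along the mediolateral (ML) axis.
#' Grid rows index the length (AP) axis and grid columns the width (ML) axis;
#' indices are 1-based.
#'
#' @param length_mm physical extent along the row (AP) axis, mm.
#' @param width_mm physical extent along the column (ML) axis, mm.
#' @param n_rows,n_cols stitched grid size.
#' @param module_shape rows/cols of one sensor module.
#' @param module_tiling how modules are tiled to form the grid.
#' @param ml_axis which physical extent the ML coordinate spans. The mat is
#'   wider along AP than ML, so the default maps ML to the width axis;
#'   `"length"` reproduces the alternative literal pairing (see
#'   [wma_cop()]'s `strict_eq1`).
#' @param cell_center if `TRUE`, coordinates use cell centers `(i - 0.5) *
#'   pitch` instead of the literal `i * pitch`.
#' @return An object of class `sensor_geometry`.
#' @examples
#' g <- sensor_geometry()
#' g$pitch_width_mm   # 600/64 = 9.375 mm
#' @export
sensor_geometry <- function(length_mm = 800, width_mm = 600,
                            n_rows = 64L, n_cols = 64L,
                            module_shape = c(32L, 32L),
                            module_tiling = c(2L, 2L),
                            ml_axis = c("width", "length"),
                            cell_center = FALSE) {
  assert_scalar_number(length_mm, "length_mm", positive = TRUE)
  assert_scalar_number(width_mm, "width_mm", positive = TRUE)
  ml_axis <- match.arg(ml_axis)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  module_shape <- as.integer(module_shape)
  module_tiling <- as.integer(module_tiling)
  if (n_rows != module_tiling[1] * module_shape[1] ||
      n_cols != module_tiling[2] * module_shape[2])
    abort_invalid("grid size must equal module_tiling * module_shape per axis")
  g <- list(
    length_mm = length_mm, width_mm = width_mm,
    n_rows = n_rows, n_cols = n_cols,
    module_shape = module_shape, module_tiling = module_tiling,
    ml_axis = ml_axis, cell_center = cell_center,
    pitch_length_mm = length_mm / n_rows,
    pitch_width_mm = width_mm / n_cols)
  class(g) <- "sensor_geometry"
  g
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat(sprintf("<sensor_geometry> %d x %d grid, %.0f x %.0f mm (pitch %.3f x %.3f mm)\n",
              x$n_rows, x$n_cols, x$length_mm, x$width_mm,
              x$pitch_length_mm, x$pitch_width_mm))
  invisible(x)
}

is_sensor_geometry <- function(x) inherits(x, "sensor_geometry")

# coordinate of a 1-based grid index along one axis
grid_coord <- function(idx, pitch, cell_center) {
  if (cell_center) (idx - 0.5) * pitch else idx * pitch
}
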