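#' Define a rectangular sampling grid
#'
#' A grid is a planar rectangle divided into square cells of edge length
#' `resolution`; communities are sampled at cell center points, mimicking
#' point sampling of range maps at regular (0.1-degree-style) intervals.
#' Coordinates are abstract planar units: no geodesy is applied anywhere
#' in the package.
#'
#' Cells are indexed row-major from the `(x_min, y_min)` corner, 0-based,
#' so `cell = iy * nx + ix`.  All tabular outputs carry explicit `x`, `y`
#' center coordinates to keep the indexing self-describing.
#'
#' @param x_min,y_min,x_max,y_max domain bounds; both extents must be
#'   positive.
#' @param resolution cell edge length (default 0.1).
#' @return An object of class `grid_spec` with fields `x_min`, `y_min`,
#'   `x_max`, `y_max`, `resolution`, `nx`, `ny`, `n_cells`.
#' @examples
#' g <- grid_spec(0, 0, 2, 1, 0.5)
#' g$n_cells # 8
#' @export
grid_spec <- function(x_min = 0, y_min = 0, x_max = 1, y_max = 1,
                      resolution = 0.1) {
  stopifnot(is_scalar_num(x_min), is_scalar_num(y_min),
            is_scalar_num(x_max), is_scalar_num(y_max),
            is_scalar_num(resolution))
  if (resolution <= 0) stop("`resolution` must be > 0")
  if (x_max <= x_min || y_max <= y_min) {
    stop("grid extents must be positive: require x_max > x_min and y_max > y_min")
  }
  nx <- max(1L, as.integer(floor((x_max - x_min) / resolution + 1e-9)))
  ny <- max(1L, as.integer(floor((y_max - y_min) / resolution + 1e-9)))
  structure(
    list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
         resolution = resolution, nx = nx, ny = ny,
         n_cells = nx * ny),
    class = "grid_spec"
  )
}

#' Cell center coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return A data frame with columns `cell` (0-based row-major index),
#'   `x`, `y` (center coordinates), one row per cell.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ix <- rep(seq_len(grid$nx) - 1L, times = grid$ny)
  iy <- rep(seq_len(grid$ny) - 1L, each = grid$nx)
  data.frame(
    cell = iy * grid$nx + ix,
    x = grid$x_min + (ix + 0.5) * grid$resolution,
    y = grid$y_min + (iy + 0.5) * grid$resolution
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: [%g, %g] x [%g, %g], resolution %g (%d x %d = %d cells)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$resolution,
              x$nx, x$ny, x$n_cells))
  invisible(x)
}
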