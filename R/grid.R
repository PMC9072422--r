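#' Sparse-noise stimulus grid geometry
#'
#' The monitor is divided into a regular grid of square tiles (18 columns by
#' 8 rows by default, each tile 8 x 8 degrees of visual angle). Tiles are
#' indexed 1-based as `(row, col)` = (elevation, azimuth), with azimuth
#' increasing rightward and elevation increasing upward; this convention is
#' used everywhere in the package. Visual-field coordinates `(y1, y2)` are
#' (azimuth, elevation) in degrees, with the origin at the lower-left corner
#' of the grid.
#'
#' @param n_rows,n_cols number of tile rows (elevation) and columns (azimuth).
#' @param tile_deg tile side length in degrees of visual angle.
#' @return An object of class `stim_grid`: a list with `n_rows`, `n_cols`,
#'   `tile_deg` and `extent = c(az_min, az_max, el_min, el_max)` in degrees.
#' @examples
#' g <- stim_grid()
#' g$extent
#' @export
stim_grid <- function(n_rows = 8L, n_cols = 18L, tile_deg = 8) {
  stopifnot(n_rows >= 1, n_cols >= 1, tile_deg > 0)
  structure(
    list(
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      tile_deg = tile_deg,
      extent = c(az_min = 0, az_max = n_cols * tile_deg,
                 el_min = 0, el_max = n_rows * tile_deg)
    ),
    class = "stim_grid"
  )
}

#' Tile-center coordinates of a stimulus grid
#'
#' @param grid a [stim_grid()].
#' @return A list with vectors `az` (length `n_cols`) and `el` (length
#'   `n_rows`) of tile-center coordinates in degrees, plus matrices `AZ`, `EL`
#'   of shape `n_rows x n_cols` giving the center of each tile.
#' @export
tile_centers <- function(grid) {
  stopifnot(inherits(grid, "stim_grid"))
  az <- (seq_len(grid$n_cols) - 0.5) * grid$tile_deg
  el <- (seq_len(grid$n_rows) - 0.5) * grid$tile_deg
  list(az = az, el = el,
       AZ = matrix(az, grid$n_rows, grid$n_cols, byrow = TRUE),
       EL = matrix(el, grid$n_rows, grid$n_cols))
}

#' Evaluate an elliptical Gaussian on the tile grid
#'
#' Utility used by the population generator: a receptive-field subregion is an
#' isotropic Gaussian of width `sigma` (degrees) centered at `(az, el)`,
#' evaluated at tile centers with peak value `amplitude`.
#'
#' @param grid a [stim_grid()].
#' @param az,el center in degrees.
#' @param sigma standard deviation in degrees.
#' @param amplitude peak value.
#' @return `n_rows x n_cols` matrix.
#' @export
gaussian_map <- function(grid, az, el, sigma, amplitude = 1) {
  tc <- tile_centers(grid)
  amplitude * exp(-((tc$AZ - az)^2 + (tc$EL - el)^2) / (2 * sigma^2))
}

#' @export
print.stim_grid <- function(x, ...) {
  cat(sprintf("Sparse-noise grid: %d rows x %d cols, tile %.3g deg\n",
              x$n_rows, x$n_cols, x$tile_deg))
  cat(sprintf("  azimuth [%g, %g] deg, elevation [%g, %g] deg\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  invisible(x)
}
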