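#' Affine retinotopy with polarity-specific scatter
#'
#' The retinotopic map carries visual-field coordinates (degrees) to cortical
#' surface coordinates (micrometers) through an invertible affine map,
#' `x = y %*% affine + offset` (row-vector convention). Individual cells
#' scatter around the mapped position with isotropic Gaussian noise whose
#' standard deviation may differ by polarity; ON cells are given at least as
#' much retinotopic scatter as OFF cells, matching the ordering reported for
#' mouse V1. Depth (`x3`) is drawn from evenly spaced optical planes.
#'
#' Defaults place an 18 x 8 tile grid (144 x 64 deg) onto a 900 x 540 um
#' imaging field with planes every 30 um from 150 to 360 um below the surface.
#'
#' @param affine invertible 2x2 matrix, um per degree, applied as
#'   `cbind(az, el) %*% affine`.
#' @param offset length-2 cortical offset in um.
#' @param scatter_sigma_on,scatter_sigma_off retinotopic scatter SD in um;
#'   `scatter_sigma_on >= scatter_sigma_off` is required.
#' @param depth_range cortical depth interval in um.
#' @param plane_spacing spacing of optical planes in um.
#' @return Object of class `retinotopy_model`.
#' @examples
#' r <- retinotopy_model()
#' retinotopy_map(r, az = 72, el = 32)  # center of the default grid
#' @export
retinotopy_model <- function(affine = diag(c(900 / 144, 540 / 64)),
                             offset = c(0, 0),
                             scatter_sigma_on = 45,
                             scatter_sigma_off = 30,
                             depth_range = c(150, 360),
                             plane_spacing = 30) {
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(2L, 2L)), length(offset) == 2)
  if (abs(det(affine)) < 1e-12) stop("'affine' must be invertible")
  if (scatter_sigma_on < scatter_sigma_off)
    stop("'scatter_sigma_on' must be >= 'scatter_sigma_off'")
  stopifnot(scatter_sigma_off >= 0, diff(depth_range) >= 0, plane_spacing > 0)
  structure(
    list(affine = affine, offset = as.numeric(offset),
         scatter_sigma_on = scatter_sigma_on,
         scatter_sigma_off = scatter_sigma_off,
         depth_range = as.numeric(depth_range),
         planes = seq(depth_range[1], depth_range[2], by = plane_spacing)),
    class = "retinotopy_model"
  )
}

#' Map visual-field positions to cortical surface positions
#'
#' Applies the noiseless affine part of a retinotopy model.
#'
#' @param model a [retinotopy_model()].
#' @param az,el visual-field coordinates in degrees.
#' @return `n x 2` matrix of cortical `(x1, x2)` positions in um.
#' @export
retinotopy_map <- function(model, az, el) {
  stopifnot(inherits(model, "retinotopy_model"))
  cbind(az, el) %*% model$affine +
    matrix(model$offset, length(az), 2, byrow = TRUE)
}

#' @export
print.retinotopy_model <- function(x, ...) {
  cat("Affine retinotopy (deg -> um):\n")
  print(round(x$affine, 3))
  cat(sprintf("  scatter SD: ON %.3g um, OFF %.3g um; %d planes at %g..%g um\n",
              x$scatter_sigma_on, x$scatter_sigma_off, length(x$planes),
              x$depth_range[1], x$depth_range[2]))
  invisible(x)
}
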