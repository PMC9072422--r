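#' Fit a two-dimensional elliptical Gaussian to a kernel map
#'
#' Least-squares fit of an elliptical (rotatable) Gaussian with a constant
#' offset, used to localize receptive-field centers `(y1, y2)` on the visual
#' field and to score kernel quality by variance explained. The model is
#' `o + A * exp(-0.5 * q(az, el))` with `q` the quadratic form of a rotated
#' anisotropic Gaussian. Initialization comes from image moments of the
#' positive excursion of the map; the center is constrained to lie within
#' one tile beyond the grid and the widths to at least a fifth of a tile.
#'
#' @param map `n_rows x n_cols` kernel map (finite, not all equal).
#' @param grid the [stim_grid()] the map lives on (supplies degree
#'   coordinates of tile centers).
#' @return Object of class `gauss2d`: list with `center` (`c(y1, y2)`, deg),
#'   `sigmas` (`c(s1, s2)`, deg, principal widths), `orientation` (radians),
#'   `amplitude`, `offset`, `variance_explained` in `[0, 1]`, `converged`,
#'   and `fitted` (the model map). A failed optimization returns
#'   `converged = FALSE` with `variance_explained = 0`.
#' @examples
#' g <- stim_grid()
#' fit <- fit_gauss2d(gaussian_map(g, 60, 30, 9), g)
#' fit$center
#' @export
fit_gauss2d <- function(map, grid = stim_grid()) {
  stopifnot(is.matrix(map), all(is.finite(map)))
  if (max(map) == min(map)) stop("map is constant; Gaussian fit undefined")
  tc <- tile_centers(grid)
  az <- as.numeric(tc$AZ); el <- as.numeric(tc$EL); z <- as.numeric(map)
  tile <- grid$tile_deg; ext <- grid$extent

  # moment initialization on the positive excursion above the median
  w <- pmax(z - stats::median(z), 0)
  if (sum(w) == 0) w <- z - min(z)
  w <- w / sum(w)
  cx0 <- sum(w * az); cy0 <- sum(w * el)
  sx0 <- sqrt(max(sum(w * (az - cx0)^2), (tile / 2)^2))
  sy0 <- sqrt(max(sum(w * (el - cy0)^2), (tile / 2)^2))
  o0 <- stats::median(z); a0 <- max(z) - o0

  model <- function(p) {
    ct <- cos(p[7]); st <- sin(p[7])
    u <- ct * (az - p[2]) + st * (el - p[3])
    v <- -st * (az - p[2]) + ct * (el - p[3])
    p[6] + p[1] * exp(-0.5 * ((u / p[4])^2 + (v / p[5])^2))
  }
  sse <- function(p) sum((z - model(p))^2)

  lower <- c(-Inf, ext[1] - tile, ext[3] - tile, tile / 5, tile / 5, -Inf, -pi)
  upper <- c(Inf, ext[2] + tile, ext[4] + tile,
             2 * (ext[2] - ext[1]), 2 * (ext[4] - ext[3]), Inf, pi)
  # two starts: image moments, and the brightest tile with a one-tile width
  peak <- which.max(z)
  starts <- list(c(a0, cx0, cy0, sx0, sy0, o0, 0),
                 c(a0, az[peak], el[peak], tile, tile, o0, 0))
  fit <- NULL
  for (p0 in starts) {
    f <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(f) && is.finite(f$value) &&
        (is.null(fit) || f$value < fit$value)) fit <- f
  }
  ss_tot <- sum((z - mean(z))^2)

  if (is.null(fit) || !is.finite(fit$value)) {
    return(structure(list(center = c(NA, NA), sigmas = c(NA, NA),
                          orientation = NA, amplitude = NA, offset = NA,
                          variance_explained = 0, converged = FALSE,
                          fitted = NULL),
                     class = "gauss2d"))
  }
  p <- fit$par
  # canonical form: sigma1 >= sigma2, orientation in (-pi/2, pi/2]
  if (p[4] < p[5]) { p[c(4, 5)] <- p[c(5, 4)]; p[7] <- p[7] + pi / 2 }
  p[7] <- ((p[7] + pi / 2) %% pi) - pi / 2
  ve <- max(0, min(1, 1 - fit$value / ss_tot))
  structure(
    list(center = c(y1 = p[2], y2 = p[3]), sigmas = c(p[4], p[5]),
         orientation = p[7], amplitude = p[1], offset = p[6],
         variance_explained = ve, converged = fit$convergence == 0,
         fitted = matrix(model(fit$par), grid$n_rows, grid$n_cols)),
    class = "gauss2d"
  )
}

#' @export
print.gauss2d <- function(x, ...) {
  if (!x$converged && x$variance_explained == 0) {
    cat("2-D Gaussian fit: failed\n"); return(invisible(x))
  }
  cat(sprintf(
    "2-D Gaussian fit: center (%.2f, %.2f) deg, sigmas (%.2f, %.2f) deg, VE %.3f\n",
    x$center[1], x$center[2], x$sigmas[1], x$sigmas[2], x$variance_explained))
  invisible(x)
}
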