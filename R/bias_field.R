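#' ON/OFF bias field over the visual field
#'
#' Constructs a smooth scalar field \eqn{b(y_1, y_2) \in [-1, 1]} over the
#' stimulated region of the visual field describing the local imbalance
#' between ON and OFF inputs: `b > 0` marks ON-dominant locations, `b < 0`
#' OFF-dominant ones. The field is a sum of `n_blobs` randomly placed signed
#' Gaussian bumps of width `length_scale`, plus a constant `imbalance`
#' offset, clipped to `[-1, 1]`. With `amplitude = 0` the field is
#' identically `imbalance` (zero by default).
#'
#' The field is the generative premise of the biased-input account of
#' cortical ON/OFF domains: the relative density of ON and OFF receptive-field
#' centers varies smoothly across the visual field, and an accurate retinotopy
#' transports those fluctuations onto the cortical surface.
#'
#' @param grid a [stim_grid()] giving the visual-field extent in degrees.
#' @param n_blobs number of Gaussian bumps.
#' @param amplitude peak height of each bump, in `[0, 1]`.
#' @param length_scale bump standard deviation in degrees; must be positive.
#' @param imbalance global ON minus OFF offset added before clipping (the
#'   spatial mean of the field stays within about 0.2 of this value).
#' @param seed integer seed for bump placement; `NULL` leaves the RNG state
#'   alone.
#' @param bumps optional data frame with columns `az`, `el`, `sign`
#'   (+1/-1) placing the bumps explicitly instead of at random;
#'   `n_blobs` and `seed` are then ignored and each bump's height is
#'   `amplitude * sign`.
#' @param spacing lattice spacing, in degrees, of the stored evaluation of
#'   the field (evaluation elsewhere is exact, from the bump parameters).
#' @return Object of class `bias_field`: list with the bump parameter table
#'   `bumps` (center, sign, height), `length_scale`, `imbalance`, `grid`,
#'   lattice vectors `az`, `el` and the clipped field `values`
#'   (`length(el) x length(az)`).
#' @examples
#' b <- make_bias_field(stim_grid(), n_blobs = 6, amplitude = 0.8, seed = 1)
#' range(b$values)
#' @seealso [bias_eval()], [sample_population()]
#' @export
make_bias_field <- function(grid = stim_grid(), n_blobs = 6, amplitude = 0.5,
                            length_scale = 25, imbalance = 0, seed = NULL,
                            bumps = NULL, spacing = 1) {
  stopifnot(inherits(grid, "stim_grid"))
  if (length_scale <= 0) stop("'length_scale' must be positive")
  if (amplitude < 0 || amplitude > 1) stop("'amplitude' must lie in [0, 1]")
  ext <- grid$extent
  if (ext[2] <= ext[1] || ext[4] <= ext[3]) stop("degenerate grid extent")
  if (!is.null(seed)) set.seed(seed)

  n_blobs <- as.integer(n_blobs)
  if (!is.null(bumps)) {
    stopifnot(all(c("az", "el", "sign") %in% names(bumps)))
    bumps <- data.frame(az = bumps$az, el = bumps$el, sign = bumps$sign,
                        height = amplitude * bumps$sign)
  } else if (n_blobs > 0) {
    # balanced signs (alternating after a random shuffle) keep the spatial
    # mean near 'imbalance' even for odd n_blobs
    signs <- rep_len(c(1, -1), n_blobs)[sample.int(n_blobs)]
    bumps <- data.frame(
      az = stats::runif(n_blobs, ext[1], ext[2]),
      el = stats::runif(n_blobs, ext[3], ext[4]),
      sign = signs,
      height = amplitude * signs
    )
  } else {
    bumps <- data.frame(az = numeric(0), el = numeric(0),
                        sign = numeric(0), height = numeric(0))
  }

  field <- structure(
    list(bumps = bumps, length_scale = length_scale, imbalance = imbalance,
         amplitude = amplitude, grid = grid),
    class = "bias_field"
  )
  field$az <- seq(ext[1], ext[2], by = spacing)
  field$el <- seq(ext[3], ext[4], by = spacing)
  pts <- expand.grid(az = field$az, el = field$el)
  field$values <- matrix(bias_eval(field, pts$az, pts$el),
                         nrow = length(field$el), ncol = length(field$az),
                         byrow = TRUE)
  field
}

#' Evaluate a bias field at visual-field locations
#'
#' @param field a [make_bias_field()] object.
#' @param az,el coordinate vectors in degrees (recycled to common length).
#' @return Numeric vector of field values in `[-1, 1]`.
#' @export
bias_eval <- function(field, az, el) {
  stopifnot(inherits(field, "bias_field"))
  v <- rep(field$imbalance, length(az))
  ls2 <- 2 * field$length_scale^2
  b <- field$bumps
  for (k in seq_len(nrow(b))) {
    v <- v + b$height[k] * exp(-((az - b$az[k])^2 + (el - b$el[k])^2) / ls2)
  }
  pmin(1, pmax(-1, v))
}

#' @export
print.bias_field <- function(x, ...) {
  cat(sprintf(
    "ON/OFF bias field: %d bumps, amplitude %.2f, length scale %.3g deg\n",
    nrow(x$bumps), x$amplitude, x$length_scale))
  cat(sprintf("  values in [%.3f, %.3f], spatial mean %.3f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}
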