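#' Regular evaluation grid for density fields
#'
#' @param xlim,ylim grid extent (um in native cortical space, dimensionless
#'   in canonical space).
#' @param spacing node spacing, same units.
#' @return Object of class `density_grid`: list with node vectors `x`, `y`,
#'   `spacing` and `extent`.
#' @export
density_grid <- function(xlim, ylim, spacing) {
  stopifnot(spacing > 0, xlim[2] > xlim[1], ylim[2] > ylim[1])
  structure(list(x = seq(xlim[1], xlim[2], by = spacing),
                 y = seq(ylim[1], ylim[2], by = spacing),
                 spacing = spacing, extent = c(xlim, ylim)),
            class = "density_grid")
}

#' Default native cortical evaluation grid
#'
#' A 900 x 540 um imaging field sampled every `spacing` um and padded by
#' `pad` (twice the 30-um density bandwidth by default) on every side.
#' @param spacing node spacing in um.
#' @param pad padding in um.
#' @export
native_grid <- function(spacing = 10, pad = 60) {
  density_grid(c(-pad, 900 + pad), c(-pad, 540 + pad), spacing)
}

#' Default canonical evaluation grid
#'
#' Both canonical axes span `[-2.5, 2.5]`, sampled every `spacing`.
#' @param spacing node spacing (dimensionless).
#' @export
canonical_grid <- function(spacing = 0.05) {
  density_grid(c(-2.5, 2.5), c(-2.5, 2.5), spacing)
}

# kernel matrix: n_nodes x n_points, entry = G_sigma(node - point); row-major
# over nodes with y varying slowest (rows of the field matrix = y nodes)
kde_kernel_matrix <- function(points, sigma, grid) {
  nx <- length(grid$x); ny <- length(grid$y)
  gx <- rep(grid$x, times = ny); gy <- rep(grid$y, each = nx)
  d2 <- outer(gx, points[, 1], `-`)^2 + outer(gy, points[, 2], `-`)^2
  exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
}

#' Two-dimensional Gaussian kernel density estimate
#'
#' The density at grid node `x` is the mean of isotropic Gaussian bumps of
#' width `sigma` centered on the data points, with no edge correction:
#' `f(x) = (1/n) * sum_i G_sigma(x - x_i)`. On a grid extending at least
#' four bandwidths past the data hull the discrete integral is within a few
#' percent of one.
#'
#' @param points `n x 2` matrix of locations (um in cortical space, degrees
#'   in visual space, dimensionless in canonical space).
#' @param sigma kernel width, same units as `points`.
#' @param grid a [density_grid()].
#' @return Object of class `density_field`: list with `values`
#'   (`length(grid$y) x length(grid$x)` matrix, y indexing rows), `grid`,
#'   `sigma`, `n_points`.
#' @export
kde2d <- function(points, sigma, grid) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("density undefined for an empty point set")
  stopifnot(sigma > 0, ncol(points) == 2, inherits(grid, "density_grid"))
  K <- kde_kernel_matrix(points, sigma, grid)
  v <- rowMeans(K)
  structure(list(values = matrix(v, length(grid$y), length(grid$x),
                                 byrow = TRUE),
                 grid = grid, sigma = sigma, n_points = nrow(points)),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf(
    "Density field: %d x %d nodes (spacing %g), sigma %g, n = %d, mass %.3f\n",
    length(x$grid$y), length(x$grid$x), x$grid$spacing, x$sigma, x$n_points,
    sum(x$values) * x$grid$spacing^2))
  invisible(x)
}

#' ON minus OFF density fluctuation map with Monte-Carlo level sets
#'
#' Computes `f_on - f_off` from the two point sets and assesses pointwise
#' significance by label-shuffle Monte Carlo: in each of `n_shuffles`
#' experiments the ON/OFF labels are randomly permuted over the pooled
#' points (group sizes fixed, positions unchanged) and the difference is
#' recomputed. The pointwise `alpha` and `1 - alpha` empirical quantiles of
#' the shuffle distribution form the null envelope; nodes where the observed
#' difference exceeds the upper envelope are flagged ON-dominant
#' (`sig_pos`), nodes below the lower envelope OFF-dominant (`sig_neg`).
#' With `alpha = 0.001` and 1000 shuffles the envelope uses the min/max
#' order statistics. If `n_shuffles < 1/alpha`, `alpha` is clamped to
#' `1/n_shuffles` with a warning.
#'
#' @param on_points,off_points `n x 2` matrices of ON / OFF cell positions.
#' @param sigma density bandwidth (30 um native, 0.25 canonical by default
#'   elsewhere).
#' @param grid a [density_grid()].
#' @param n_shuffles Monte-Carlo shuffle count.
#' @param alpha pointwise significance level.
#' @param seed integer seed for the shuffles; `NULL` leaves the RNG alone.
#' @return Object of class `fluctuation_map`: list with `values`,
#'   `null_low`, `null_high` (matrices on the grid), logical masks
#'   `sig_pos`, `sig_neg`, and `f_on`, `f_off` [kde2d()] fields, plus
#'   `grid`, `sigma`, `n_shuffles`, `alpha`, `n_on`, `n_off`.
#' @export
fluctuation_map <- function(on_points, off_points, sigma, grid,
                            n_shuffles = 1000, alpha = 0.001, seed = NULL) {
  on_points <- as.matrix(on_points); off_points <- as.matrix(off_points)
  if (nrow(on_points) < 1 || nrow(off_points) < 1)
    stop("both ON and OFF point sets must be non-empty")
  if (n_shuffles < 1 / alpha) {
    warning(sprintf(
      "n_shuffles = %d cannot resolve alpha = %g; clamping alpha to %g",
      n_shuffles, alpha, 1 / n_shuffles))
    alpha <- 1 / n_shuffles
  }
  if (!is.null(seed)) set.seed(seed)
  n_on <- nrow(on_points); n_off <- nrow(off_points); n <- n_on + n_off
  pooled <- rbind(on_points, off_points)
  is_on <- c(rep(TRUE, n_on), rep(FALSE, n_off))
  # canonical point order (independent of which polarity came first), so a
  # swapped ON/OFF call draws exactly complementary shuffle subsets and the
  # significance masks exchange exactly, not just in distribution
  ord <- order(pooled[, 1], pooled[, 2], !is_on)
  pooled <- pooled[ord, , drop = FALSE]; is_on <- is_on[ord]
  K <- kde_kernel_matrix(pooled, sigma, grid)   # nodes x cells

  w_obs <- ifelse(is_on, 1 / n_on, -1 / n_off)
  # shuffle weights, cells x n_shuffles: each shuffle takes the smaller group
  # from the front of a fresh permutation (for equal group sizes, antithetic
  # complement pairs keep the null closed under label exchange)
  if (n_on != n_off) {
    n_small <- min(n_on, n_off)
    small_is_on <- n_on < n_off
    W <- vapply(seq_len(n_shuffles), function(s) {
      idx <- sample.int(n)[seq_len(n_small)]
      w <- rep(if (small_is_on) -1 / n_off else 1 / n_on, n)
      w[idx] <- if (small_is_on) 1 / n_on else -1 / n_off
      w
    }, numeric(n))
  } else {
    m <- ceiling(n_shuffles / 2)
    n_shuffles <- 2L * m
    W <- matrix(0, n, n_shuffles)
    for (i in seq_len(m)) {
      idx <- sample.int(n)[seq_len(n_on)]
      w <- rep(-1 / n_off, n); w[idx] <- 1 / n_on
      W[, 2L * i - 1L] <- w
      W[, 2L * i] <- -w
    }
  }
  null_vals <- K %*% W                           # nodes x shuffles
  obs <- as.numeric(K %*% w_obs)

  lo_k <- max(1L, floor(alpha * n_shuffles))
  hi_k <- min(n_shuffles, n_shuffles - lo_k + 1L)
  null_sorted <- apply(null_vals, 1, sort)       # shuffles x nodes
  low <- null_sorted[lo_k, ]
  high <- null_sorted[hi_k, ]

  to_m <- function(v) matrix(v, length(grid$y), length(grid$x), byrow = TRUE)
  structure(
    list(values = to_m(obs), null_low = to_m(low), null_high = to_m(high),
         sig_pos = to_m(obs > high), sig_neg = to_m(obs < low),
         f_on = kde2d(on_points, sigma, grid),
         f_off = kde2d(off_points, sigma, grid),
         grid = grid, sigma = sigma, n_shuffles = n_shuffles, alpha = alpha,
         n_on = n_on, n_off = n_off),
    class = "fluctuation_map"
  )
}

#' @export
print.fluctuation_map <- function(x, ...) {
  cat(sprintf(
    "ON-OFF fluctuation map: %d ON, %d OFF cells, sigma %g, %d shuffles (alpha %g)\n",
    x$n_on, x$n_off, x$sigma, x$n_shuffles, x$alpha))
  cat(sprintf("  flagged nodes: %d ON-dominant, %d OFF-dominant of %d\n",
              sum(x$sig_pos), sum(x$sig_neg), length(x$values)))
  invisible(x)
}

#' @export
plot.fluctuation_map <- function(x, ...) {
  graphics::image(x$grid$x, x$grid$y, t(x$values),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "x1", ylab = "x2",
                  main = "ON - OFF density fluctuation", useRaster = TRUE, ...)
  if (any(x$sig_pos))
    graphics::contour(x$grid$x, x$grid$y, t(x$sig_pos * 1), levels = 0.999,
                      col = "red3", add = TRUE, drawlabels = FALSE)
  if (any(x$sig_neg))
    graphics::contour(x$grid$x, x$grid$y, t(x$sig_neg * 1), levels = 0.999,
                      col = "blue3", add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' Extract significant ON/OFF domains as polygons
#'
#' Traces closed contours around each significance mask of a fluctuation
#' map and measures their areas. Contours are traced through the outermost
#' flagged grid nodes (marching squares on the mask indicator at a level
#' just below one, so the polygon passes through node centers); contours
#' that would leave the grid are closed along its boundary by zero-padding.
#' Areas use the shoelace formula in grid units squared.
#'
#' @param fluct a [fluctuation_map()].
#' @return Object of class `domain_set`: data frame `domains` with one row
#'   per polygon (`polarity` "ON"/"OFF", `area`, centroid `cx`, `cy`,
#'   `n_nodes` flagged nodes enclosed) and a list `polygons` of `x`/`y`
#'   coordinate lists. Empty masks yield zero polygons.
#' @export
extract_level_sets <- function(fluct) {
  stopifnot(inherits(fluct, "fluctuation_map"))
  polys <- list(); rows <- list()
  for (pol in c("ON", "OFF")) {
    mask <- if (pol == "ON") fluct$sig_pos else fluct$sig_neg
    cl <- mask_contours(mask, fluct$grid)
    for (p in cl) {
      a <- shoelace_area(p$x, p$y)
      inside <- points_in_poly(fluct$grid, mask, p)
      polys[[length(polys) + 1L]] <- p
      rows[[length(rows) + 1L]] <- data.frame(
        polarity = pol, area = a, cx = mean(p$x), cy = mean(p$y),
        n_nodes = inside, stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(rows)) do.call(rbind, rows)
             else data.frame(polarity = character(0), area = numeric(0),
                             cx = numeric(0), cy = numeric(0),
                             n_nodes = integer(0))
  structure(list(domains = domains, polygons = polys, grid = fluct$grid),
            class = "domain_set")
}

mask_contours <- function(mask, grid, level = 1 - 1e-3) {
  if (!any(mask)) return(list())
  # zero-pad one node ring so every contour closes inside the lattice
  sp <- grid$spacing
  z <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  z[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  xs <- c(grid$x[1] - sp, grid$x, grid$x[length(grid$x)] + sp)
  ys <- c(grid$y[1] - sp, grid$y, grid$y[length(grid$y)] + sp)
  grDevices::contourLines(xs, ys, t(z), levels = level)
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

points_in_poly <- function(grid, mask, poly) {
  # count flagged nodes inside the polygon bounding box (cheap containment
  # proxy adequate for reporting; polygons from disjoint masks do not nest)
  nx <- length(grid$x)
  idx <- which(mask, arr.ind = TRUE)
  px <- grid$x[idx[, 2]]; py <- grid$y[idx[, 1]]
  sum(px >= min(poly$x) & px <= max(poly$x) &
      py >= min(poly$y) & py <= max(poly$y))
}

#' @export
print.domain_set <- function(x, ...) {
  d <- x$domains
  cat(sprintf("Domain set: %d polygons (%d ON, %d OFF)\n",
              nrow(d), sum(d$polarity == "ON"), sum(d$polarity == "OFF")))
  if (nrow(d))
    cat(sprintf("  median area: %.4g (ON), %.4g (OFF)\n",
                stats::median(d$area[d$polarity == "ON"]),
                stats::median(d$area[d$polarity == "OFF"])))
  invisible(x)
}

#' Split-half depth test of domain columnarity
#'
#' Splits the population at the median optical plane, computes the ON-OFF
#' fluctuation values (no masks) separately for the top and bottom halves on
#' a shared grid, and correlates them across grid nodes. If ON/OFF domains
#' are columnar, the two half-maps correlate positively. The p-value comes
#' from a shuffle null in which ON/OFF labels are permuted independently
#' within each half and the correlation recomputed (one-sided, greater).
#'
#' @param cells data frame with columns `x1`, `x2`, `x3` (um) and `class`
#'   ("ON"/"OFF"; other classes ignored).
#' @param sigma density bandwidth in um.
#' @param grid a [density_grid()].
#' @param n_shuffles shuffle count for the null.
#' @param seed integer seed; `NULL` leaves the RNG alone.
#' @return List with `pearson_r`, `p_value`, `depth_split` (um), and the two
#'   half-map value matrices `top`, `bottom`.
#' @export
split_half_columnarity <- function(cells, sigma = 30, grid = native_grid(),
                                   n_shuffles = 1000, seed = NULL) {
  cells <- cells[cells$class %in% c("ON", "OFF"), , drop = FALSE]
  if (length(unique(cells$x3)) < 2)
    stop("need at least 2 distinct optical planes to split by depth")
  if (!is.null(seed)) set.seed(seed)
  med <- stats::median(unique(cells$x3))
  top <- cells[cells$x3 <= med, , drop = FALSE]
  bottom <- cells[cells$x3 > med, , drop = FALSE]
  for (h in list(top, bottom)) {
    if (!any(h$class == "ON") || !any(h$class == "OFF"))
      stop("a depth half has no ON or no OFF cells; split-half map undefined")
  }
  half_setup <- function(h) {
    pts <- as.matrix(h[, c("x1", "x2")])
    K <- kde_kernel_matrix(pts, sigma, grid)
    lab <- h$class == "ON"
    list(K = K, lab = lab,
         w = ifelse(lab, 1 / sum(lab), -1 / sum(!lab)))
  }
  st <- half_setup(top); sb <- half_setup(bottom)
  vt <- as.numeric(st$K %*% st$w); vb <- as.numeric(sb$K %*% sb$w)
  r_obs <- stats::cor(vt, vb)
  shuffle_w <- function(s) {
    n_on <- sum(s$lab); n <- length(s$lab)
    idx <- sample.int(n, n_on)
    w <- rep(-1 / (n - n_on), n); w[idx] <- 1 / n_on
    w
  }
  r_null <- vapply(seq_len(n_shuffles), function(i) {
    stats::cor(as.numeric(st$K %*% shuffle_w(st)),
               as.numeric(sb$K %*% shuffle_w(sb)))
  }, numeric(1))
  list(pearson_r = r_obs,
       p_value = (1 + sum(r_null >= r_obs)) / (n_shuffles + 1),
       depth_split = med,
       top = matrix(vt, length(grid$y), length(grid$x), byrow = TRUE),
       bottom = matrix(vb, length(grid$y), length(grid$x), byrow = TRUE))
}
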