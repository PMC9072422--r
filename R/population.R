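#' Sample a ground-truth V1 population
#'
#' Generates a virtual population of cortical neurons with known
#' receptive-field structure, for use as ground truth by every analysis
#' stage. Mono-contrast ON and OFF cells have receptive-field centers drawn
#' from a base-uniform density modulated by the bias field — ON centers from
#' a density proportional to `1 + b(y)`, OFF centers from `1 - b(y)` — and a
#' single Gaussian subregion of the corresponding polarity. Cortical
#' positions follow the affine retinotopy plus polarity-specific scatter,
#' with depth drawn from the model's optical planes.
#'
#' Simple cells are built as non-negative combinations of up to three nearby
#' mono-contrast ON and up to three nearby OFF ground-truth receptive fields
#' (neighbors by 3-D cortical distance), with weights drawn from a sparse
#' Dirichlet prior (`concentration < 1`). A draw is accepted only when the
#' generating ON and OFF subregion centroids are separated by more than 0.5
#' normalized distance (distance over mean Gaussian width), so every simple
#' cell has spatially displaced subregions; draws that fail fall back to
#' displaced-anchor component selection. Complex cells receive co-centered
#' ON and OFF Gaussians (normalized separation 0).
#'
#' @param bias a [make_bias_field()] object.
#' @param retinotopy a [retinotopy_model()].
#' @param n_on,n_off,n_simple,n_complex cell counts per class (>= 0).
#' @param rf_sigma mean receptive-field subregion width in degrees; each
#'   cell's width is jittered by +/-15 percent.
#' @param dirichlet_conc concentration of the sparse weight prior (< 1).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `v1_population`: list with `cells` (data frame:
#'   `id`, `class`, `x1`,`x2`,`x3` um, `y1`,`y2` deg overall center,
#'   `on_y1`,`on_y2`,`off_y1`,`off_y2` per-polarity generating centers,
#'   `rf_sigma`), `maps` (per cell, list with `on` and/or `off` ground-truth
#'   maps on the stimulus grid), `weights` (per simple cell: component ids
#'   and non-negative weights per polarity), plus `bias`, `retinotopy`,
#'   `grid`, `seed`.
#' @examples
#' pop <- sample_population(make_bias_field(amplitude = 0, seed = 1),
#'                          retinotopy_model(), 40, 40, 10, 10, seed = 1)
#' table(pop$cells$class)
#' @export
sample_population <- function(bias, retinotopy,
                              n_on = 270, n_off = 550,
                              n_simple = 90, n_complex = 90,
                              rf_sigma = 8, dirichlet_conc = 0.3,
                              seed = NULL) {
  stopifnot(inherits(bias, "bias_field"), inherits(retinotopy, "retinotopy_model"))
  counts <- c(n_on, n_off, n_simple, n_complex)
  if (any(counts < 0)) stop("cell counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  grid <- bias$grid

  on_centers <- sample_rf_centers(bias, n_on, polarity = "ON")
  off_centers <- sample_rf_centers(bias, n_off, polarity = "OFF")

  cells <- list(); maps <- list(); weights <- list()
  id <- 0L

  add_cell <- function(class, x, y_overall, on_center, off_center, sig,
                       on_map, off_map, w = NULL) {
    id <<- id + 1L
    cells[[id]] <<- data.frame(
      id = id, class = class, x1 = x[1], x2 = x[2], x3 = x[3],
      y1 = y_overall[1], y2 = y_overall[2],
      on_y1 = on_center[1], on_y2 = on_center[2],
      off_y1 = off_center[1], off_y2 = off_center[2],
      rf_sigma = sig, stringsAsFactors = FALSE)
    maps[[id]] <<- list(on = on_map, off = off_map)
    weights[[id]] <<- w
    invisible(id)
  }

  # --- mono-contrast cells -------------------------------------------------
  for (pol in c("ON", "OFF")) {
    centers <- if (pol == "ON") on_centers else off_centers
    sc <- if (pol == "ON") retinotopy$scatter_sigma_on else retinotopy$scatter_sigma_off
    for (i in seq_len(nrow(centers))) {
      y <- as.numeric(centers[i, ])
      sig <- rf_sigma * stats::runif(1, 0.85, 1.15)
      x12 <- retinotopy_map(retinotopy, y[1], y[2]) + stats::rnorm(2, 0, sc)
      x3 <- sample(retinotopy$planes, 1)
      m <- gaussian_map(grid, y[1], y[2], sig)
      if (pol == "ON")
        add_cell("ON", c(x12, x3), y, y, c(NA, NA), sig, m, NULL)
      else
        add_cell("OFF", c(x12, x3), y, c(NA, NA), y, sig, NULL, m)
    }
  }

  mono <- do.call(rbind, cells)
  mono_on <- mono[mono$class == "ON", , drop = FALSE]
  mono_off <- mono[mono$class == "OFF", , drop = FALSE]

  # --- simple cells --------------------------------------------------------
  if (n_simple > 0) {
    if (nrow(mono_on) < 3 || nrow(mono_off) < 3)
      stop("too few mono-contrast cells to build composite (simple) cells")
    base <- sample_rf_centers(NULL, 10 * n_simple, polarity = "BASE", grid = grid)
    bi <- 0L
    for (i in seq_len(n_simple)) {
      built <- FALSE
      for (try in seq_len(60)) {
        bi <- bi %% nrow(base) + 1L
        y <- as.numeric(base[bi, ])
        x12 <- retinotopy_map(retinotopy, y[1], y[2]) +
          stats::rnorm(2, 0, retinotopy$scatter_sigma_off)
        x3 <- sample(retinotopy$planes, 1)
        x <- c(x12, x3)
        if (try <= 30) {
          comp_on <- cluster_components(mono_on, x, sample(1:3, 1), rf_sigma)
          comp_off <- cluster_components(mono_off, x, sample(1:3, 1), rf_sigma)
        } else {
          # displaced anchors: force the two subregions apart along a random
          # direction when proximity-based draws keep landing co-centered
          u <- stats::rnorm(2); u <- u / sqrt(sum(u^2))
          d <- 1.2 * rf_sigma
          a_on <- retinotopy_map(retinotopy, y[1] + d * u[1] / 2, y[2] + d * u[2] / 2)
          a_off <- retinotopy_map(retinotopy, y[1] - d * u[1] / 2, y[2] - d * u[2] / 2)
          comp_on <- cluster_components(mono_on, c(a_on, x3), sample(1:3, 1), rf_sigma)
          comp_off <- cluster_components(mono_off, c(a_off, x3), sample(1:3, 1), rf_sigma)
        }
        w_on <- rdirichlet1(nrow(comp_on), dirichlet_conc)
        w_off <- rdirichlet1(nrow(comp_off), dirichlet_conc)
        c_on <- c(sum(w_on * comp_on$y1), sum(w_on * comp_on$y2))
        c_off <- c(sum(w_off * comp_off$y1), sum(w_off * comp_off$y2))
        sig_bar <- mean(c(sum(w_on * comp_on$rf_sigma),
                          sum(w_off * comp_off$rf_sigma)))
        nd <- sqrt(sum((c_on - c_off)^2)) / sig_bar
        if (nd > 0.5) {
          on_map <- Reduce(`+`, Map(function(j, w) w * maps[[j]]$on,
                                    comp_on$id, w_on))
          off_map <- Reduce(`+`, Map(function(j, w) w * maps[[j]]$off,
                                     comp_off$id, w_off))
          add_cell("SIMPLE", x, (c_on + c_off) / 2, c_on, c_off, sig_bar,
                   on_map, off_map,
                   w = list(on_ids = comp_on$id, on_w = w_on,
                            off_ids = comp_off$id, off_w = w_off))
          built <- TRUE
          break
        }
      }
      if (!built)
        stop("failed to synthesize a simple cell with separated subregions; ",
             "mono-contrast pool too small or too clustered")
    }
  }

  # --- complex cells -------------------------------------------------------
  if (n_complex > 0) {
    base <- sample_rf_centers(NULL, n_complex, polarity = "BASE", grid = grid)
    for (i in seq_len(n_complex)) {
      y <- as.numeric(base[i, ])
      sig <- rf_sigma * stats::runif(1, 0.85, 1.15)
      x12 <- retinotopy_map(retinotopy, y[1], y[2]) +
        stats::rnorm(2, 0, retinotopy$scatter_sigma_off)
      x3 <- sample(retinotopy$planes, 1)
      m <- gaussian_map(grid, y[1], y[2], sig)
      add_cell("COMPLEX", c(x12, x3), y, y, y, sig, m, m)
    }
  }

  structure(
    list(cells = do.call(rbind, cells), maps = maps, weights = weights,
         bias = bias, retinotopy = retinotopy, grid = grid, seed = seed),
    class = "v1_population"
  )
}

# Rejection sampler for RF centers: base density uniform over the grid
# extent, multiplied by (1 + b) for ON and (1 - b) for OFF.
sample_rf_centers <- function(bias, n, polarity, grid = bias$grid) {
  ext <- grid$extent
  if (n == 0) return(data.frame(y1 = numeric(0), y2 = numeric(0)))
  if (polarity == "BASE" || is.null(bias)) {
    return(data.frame(y1 = stats::runif(n, ext[1], ext[2]),
                      y2 = stats::runif(n, ext[3], ext[4])))
  }
  sgn <- if (polarity == "ON") 1 else -1
  dens_max <- max(1 + sgn * bias$values)
  if (dens_max < 1e-8)
    stop(sprintf("%s sampling density vanishes everywhere under this bias field (unnormalizable)",
                 polarity))
  out <- matrix(NA_real_, 0, 2)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L)
      stop(sprintf("rejection sampling for %s centers failed to converge", polarity))
    m <- max(2L * (n - nrow(out)), 64L)
    y1 <- stats::runif(m, ext[1], ext[2])
    y2 <- stats::runif(m, ext[3], ext[4])
    keep <- stats::runif(m) * dens_max < 1 + sgn * bias_eval(bias, y1, y2)
    out <- rbind(out, cbind(y1[keep], y2[keep]))
  }
  data.frame(y1 = out[seq_len(n), 1], y2 = out[seq_len(n), 2])
}

# k nearest mono-contrast cells to a 3-D cortical position
nearest_mono <- function(mono, x, k) {
  d <- sqrt((mono$x1 - x[1])^2 + (mono$x2 - x[2])^2 + (mono$x3 - x[3])^2)
  ord <- order(d, mono$id)
  mono[ord[seq_len(min(k, nrow(mono)))], , drop = FALSE]
}

# components of a composite subregion: the cortical-nearest mono cell seeds
# the subregion; further cortical neighbors join only if their RF centers lie
# within one subregion width of the seed's, so a subunit stays single-lobed
# (a cortical cell wires inputs whose centers fall inside its subregion)
cluster_components <- function(mono, x, k, rf_sigma) {
  cand <- nearest_mono(mono, x, max(2 * k, 6))
  seed <- cand[1, , drop = FALSE]
  if (k > 1 && nrow(cand) > 1) {
    rest <- cand[-1, , drop = FALSE]
    near <- sqrt((rest$y1 - seed$y1)^2 + (rest$y2 - seed$y2)^2) <= rf_sigma
    cand <- rbind(seed, rest[near, , drop = FALSE])
  }
  cand[seq_len(min(k, nrow(cand))), , drop = FALSE]
}

# one draw from a symmetric Dirichlet
rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  if (sum(g) == 0) g[sample.int(k, 1)] <- 1
  g / sum(g)
}

#' @export
print.v1_population <- function(x, ...) {
  tab <- table(x$cells$class)
  cat(sprintf("Synthetic V1 population: %d cells\n", nrow(x$cells)))
  for (cl in names(tab)) cat(sprintf("  %-8s %d\n", cl, tab[[cl]]))
  cat(sprintf("  bias amplitude %.2f, scatter ON/OFF %.3g/%.3g um\n",
              x$bias$amplitude, x$retinotopy$scatter_sigma_on,
              x$retinotopy$scatter_sigma_off))
  invisible(x)
}
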