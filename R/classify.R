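#' Classify a cell from its ON and OFF kernels
#'
#' A polarity is significant when its normalized norm curve attains a peak
#' larger than `norm_threshold` (default 5) and the 2-D Gaussian fit at the
#' peak delay explains at least `ve_threshold` (default 50 percent) of the
#' map variance. Cells with one significant polarity are mono-contrast ON or
#' OFF; cells with both are split into simple and complex by the normalized
#' distance between the two Gaussian centers — the center separation divided
#' by the average Gaussian standard deviation (the mean of each fit's two
#' principal widths, averaged across the two fits). Simple cells exceed
#' `simple_threshold` (default one half); complex cells do not. Cells with
#' no significant kernel are class `NONE` and are excluded downstream.
#'
#' @param on_stack,off_stack `kernel_stack` objects, or `NULL` when absent.
#' @param on_fit,off_fit matching [fit_gauss2d()] results (or `NULL`).
#' @param norm_threshold peak of `S(t)` required for significance.
#' @param ve_threshold minimum Gaussian-fit variance explained.
#' @param simple_threshold normalized-distance boundary between simple and
#'   complex.
#' @return Object of class `cell_classification`: list with `cell_id`,
#'   `has_on`, `has_off`, `class` in `{"ON","OFF","SIMPLE","COMPLEX","NONE"}`
#'   and `normalized_distance` (defined only when both kernels significant,
#'   otherwise `NA`).
#' @export
classify_cell <- function(on_stack = NULL, on_fit = NULL,
                          off_stack = NULL, off_fit = NULL,
                          norm_threshold = 5, ve_threshold = 0.5,
                          simple_threshold = 0.5) {
  sig <- function(stack, fit) {
    !is.null(stack) && !is.null(fit) &&
      max(stack$norm_curve) > norm_threshold &&
      fit$variance_explained >= ve_threshold
  }
  has_on <- sig(on_stack, on_fit)
  has_off <- sig(off_stack, off_fit)
  nd <- NA_real_
  cls <- "NONE"
  if (has_on && has_off) {
    sep <- sqrt(sum((on_fit$center - off_fit$center)^2))
    sig_bar <- mean(c(mean(on_fit$sigmas), mean(off_fit$sigmas)))
    nd <- sep / sig_bar
    cls <- if (nd > simple_threshold) "SIMPLE" else "COMPLEX"
  } else if (has_on) cls <- "ON" else if (has_off) cls <- "OFF"
  cell_id <- if (!is.null(on_stack)) on_stack$cell_id
             else if (!is.null(off_stack)) off_stack$cell_id else NA
  structure(list(cell_id = cell_id, has_on = has_on, has_off = has_off,
                 class = cls, normalized_distance = nd),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  cat(sprintf("cell %s: %s%s\n", x$cell_id, x$class,
              if (is.finite(x$normalized_distance))
                sprintf(" (normalized distance %.2f)", x$normalized_distance)
              else ""))
  invisible(x)
}

#' Classify every cell in a kernel set
#'
#' Runs [fit_gauss2d()] on each significant-candidate peak map and
#' [classify_cell()] per cell, returning the per-cell summary table used by
#' all downstream stages (domain maps, CCA alignment, receptive-field
#' modeling).
#'
#' @param kernels output of [estimate_kernels()].
#' @param grid the [stim_grid()] of the kernels.
#' @param norm_threshold,ve_threshold,simple_threshold see [classify_cell()].
#' @return A data frame with one row per cell: `cell_id`, `class`, `has_on`,
#'   `has_off`, per-polarity `*_peak_delay`, `*_smax` (peak of `S`),
#'   `*_ve`, centers `on_y1, on_y2, off_y1, off_y2` (deg), mean widths
#'   `on_sigma`, `off_sigma` (deg), and `normalized_distance`. Classed
#'   `classification_table` (also a data frame).
#' @export
classify_population <- function(kernels, grid = stim_grid(),
                                norm_threshold = 5, ve_threshold = 0.5,
                                simple_threshold = 0.5) {
  rows <- lapply(seq_along(kernels), function(i) {
    ks <- kernels[[i]]
    fits <- lapply(c("on", "off"), function(pol) {
      st <- ks[[pol]]
      if (is.null(st) || max(st$peak_map) == min(st$peak_map)) return(NULL)
      fit_gauss2d(st$peak_map, grid)
    })
    cl <- classify_cell(ks$on, fits[[1]], ks$off, fits[[2]],
                        norm_threshold, ve_threshold, simple_threshold)
    stat <- function(st, fit, field) {
      switch(field,
        peak = if (is.null(st)) NA_real_ else st$peak_delay,
        smax = if (is.null(st)) NA_real_ else max(st$norm_curve),
        ve = if (is.null(fit)) NA_real_ else fit$variance_explained,
        y1 = if (is.null(fit)) NA_real_ else fit$center[1],
        y2 = if (is.null(fit)) NA_real_ else fit$center[2],
        sigma = if (is.null(fit)) NA_real_ else mean(fit$sigmas))
    }
    data.frame(
      cell_id = i, class = cl$class, has_on = cl$has_on, has_off = cl$has_off,
      on_peak_delay = stat(ks$on, fits[[1]], "peak"),
      on_smax = stat(ks$on, fits[[1]], "smax"),
      on_ve = stat(ks$on, fits[[1]], "ve"),
      on_y1 = stat(ks$on, fits[[1]], "y1"),
      on_y2 = stat(ks$on, fits[[1]], "y2"),
      on_sigma = stat(ks$on, fits[[1]], "sigma"),
      off_peak_delay = stat(ks$off, fits[[2]], "peak"),
      off_smax = stat(ks$off, fits[[2]], "smax"),
      off_ve = stat(ks$off, fits[[2]], "ve"),
      off_y1 = stat(ks$off, fits[[2]], "y1"),
      off_y2 = stat(ks$off, fits[[2]], "y2"),
      off_sigma = stat(ks$off, fits[[2]], "sigma"),
      normalized_distance = cl$normalized_distance,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("classification_table", class(out))
  out
}

#' Coarse 3 x 3 retinotopy from sector-averaged signals
#'
#' Reproduces the session-start retinotopy check: the microscope's field of
#' view is split into a 3 x 3 grid of sectors, the raw signal is averaged
#' within each sector, and each sector's aggregate receptive field is mapped
#' by triggered averaging over probe locations. The sector's center is the
#' centroid of the aggregate map thresholded at half its maximum; a flat
#' aggregate map leaves that sector's center undefined.
#'
#' @param sector_signals `n_trials x 9` matrix of sector-averaged response
#'   amplitudes, sectors in row-major order (row 1 = top).
#' @param probe_positions `n_trials x 2` matrix of probe locations
#'   (azimuth, elevation) in degrees.
#' @return A `9 x 2` matrix of sector receptive-field centers in degrees
#'   (`NA` rows where undefined), with attribute `maps`: a list of per-sector
#'   data frames (probe position, mean response).
#' @export
aggregate_retinotopy <- function(sector_signals, probe_positions) {
  sector_signals <- as.matrix(sector_signals)
  probe_positions <- as.matrix(probe_positions)
  stopifnot(ncol(sector_signals) == 9, ncol(probe_positions) == 2,
            nrow(sector_signals) == nrow(probe_positions))
  key <- paste(probe_positions[, 1], probe_positions[, 2])
  upos <- !duplicated(key)
  centers <- matrix(NA_real_, 9, 2,
                    dimnames = list(NULL, c("az", "el")))
  maps <- vector("list", 9)
  for (s in 1:9) {
    m <- tapply(sector_signals[, s], key, mean)
    pos <- probe_positions[upos, , drop = FALSE][match(names(m), key[upos]), ]
    maps[[s]] <- data.frame(az = pos[, 1], el = pos[, 2], resp = as.numeric(m))
    if (max(m) > min(m) && max(m) > 0) {
      w <- as.numeric(m)
      w[w < max(w) / 2] <- 0
      centers[s, ] <- c(sum(w * pos[, 1]) / sum(w), sum(w * pos[, 2]) / sum(w))
    }
  }
  attr(centers, "maps") <- maps
  centers
}
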