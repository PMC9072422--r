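#' Estimate ON and OFF kernels by event-triggered averaging
#'
#' For every cell, polarity and delay `t` in `0:max_delay`, the kernel map
#' entry at tile `(i, j)` is the average activity `t` microscope frames after
#' the onsets of stimuli whose tile `(i, j)` was bright (ON kernel) or dark
#' (OFF kernel). The delay window spans the second following stimulus onset
#' (15 frames at 15.6 Hz by default). Tiles that were never bright (or dark)
#' over the ensemble are imputed as 0 and reported in a warning.
#'
#' @param responses a [simulate_responses()] object, or any list with a
#'   non-negative `activity` matrix (cells x microscope frames).
#' @param stimulus the [make_stimulus()] ensemble that evoked the activity.
#' @param max_delay largest delay (frames) after onset; the record must cover
#'   `max(onset) + max_delay` frames.
#' @return A list of length `n_cells`; each element is a list with `on` and
#'   `off` entries of class `kernel_stack` (fields `maps`, an
#'   `(max_delay+1) x n_rows x n_cols` array; `norm_curve` `S(t)`;
#'   `peak_delay`; `peak_map`; `polarity`; `cell_id`; `degenerate`, true when
#'   the delay-0 norm vanished and an epsilon floor was used).
#' @seealso [norm_curve()], [classify_population()]
#' @export
estimate_kernels <- function(responses, stimulus, max_delay = 15) {
  stopifnot(inherits(stimulus, "sparse_noise_stimulus"))
  act <- responses$activity
  onsets <- stimulus$onset_frame_index
  if (max(onsets) + max_delay > ncol(act))
    stop("response record too short for the requested delay window")
  n_cells <- nrow(act)
  n_stim <- dim(stimulus$frames)[1]
  g <- stimulus$grid
  n_tiles <- g$n_rows * g$n_cols
  S <- matrix(stimulus$frames, n_stim, n_tiles)

  out <- vector("list", n_cells)
  n_imputed <- 0L
  for (pol in c("on", "off")) {
    ind <- if (pol == "on") (S == 1) * 1 else (S == -1) * 1
    counts <- colSums(ind)
    zero <- counts == 0
    n_imputed <- n_imputed + sum(zero)
    counts[zero] <- 1  # imputed as 0 below (numerator is 0 there too)
    maps_t <- vector("list", max_delay + 1L)
    for (t in 0:max_delay) {
      R <- act[, onsets + t, drop = FALSE]        # cells x stimuli
      maps_t[[t + 1L]] <- (R %*% ind) / matrix(counts, n_cells, n_tiles, byrow = TRUE)
    }
    for (i in seq_len(n_cells)) {
      maps <- array(0, dim = c(max_delay + 1L, g$n_rows, g$n_cols))
      for (t in 0:max_delay)
        maps[t + 1L, , ] <- matrix(maps_t[[t + 1L]][i, ], g$n_rows, g$n_cols)
      if (is.null(out[[i]])) out[[i]] <- list()
      out[[i]][[pol]] <- new_kernel_stack(maps, toupper(pol), i)
    }
  }
  if (n_imputed > 0)
    warning(sprintf("%d tile-polarity combination(s) had no qualifying stimuli; entries imputed as 0",
                    as.integer(n_imputed)))
  out
}

new_kernel_stack <- function(maps, polarity, cell_id) {
  nc <- norm_curve_raw(maps)
  structure(
    list(maps = maps, polarity = polarity, cell_id = cell_id,
         norm_curve = nc$S, peak_delay = nc$peak_delay,
         peak_map = maps[nc$peak_delay + 1L, , ], degenerate = nc$degenerate),
    class = "kernel_stack"
  )
}

norm_curve_raw <- function(maps) {
  n_delay <- dim(maps)[1]
  norms <- vapply(seq_len(n_delay),
                  function(t) sqrt(sum(maps[t, , ]^2)), numeric(1))
  degenerate <- norms[1] <= 0
  if (degenerate) {
    # pre-response baseline norm vanished (noiseless simulations); a
    # machine-epsilon-scaled floor keeps S(t) defined and very large
    floor_val <- max(max(norms), 1) * sqrt(.Machine$double.eps)
    norms[1] <- floor_val
  }
  S <- norms / norms[1]
  list(S = S, peak_delay = which.max(S) - 1L, degenerate = degenerate)
}

#' Normalized kernel-norm curve and optimal delay
#'
#' `S(t) = ||K(t)|| / ||K(0)||` with the Frobenius norm, anchored at the
#' pre-response map at stimulus onset. The optimal (peak) delay is the
#' argmax of `S`, ties broken toward the smaller delay. These curves
#' typically peak about 5 frames (roughly 320 ms at 15.6 Hz) after onset.
#' When `||K(0)||` is exactly zero (possible only in noiseless simulations)
#' a machine-epsilon-scaled floor is substituted and the stack is flagged
#' `degenerate`.
#'
#' @param stack a `kernel_stack` from [estimate_kernels()].
#' @return List with `S` (length `max_delay + 1`, `S[1] = 1`), `peak_delay`
#'   (0-based frames) and `degenerate`.
#' @export
norm_curve <- function(stack) {
  stopifnot(inherits(stack, "kernel_stack"))
  list(S = stack$norm_curve, peak_delay = stack$peak_delay,
       degenerate = stack$degenerate)
}

#' Signed receptive field of a dual-polarity cell
#'
#' The linear receptive field of a simple cell is the difference between its
#' ON and OFF kernels at their respective peak delays; for displaced
#' subregions this shows adjacent flanks of opposite sign. Usable for
#' complex cells as well when requested.
#'
#' @param on_stack,off_stack `kernel_stack` objects for the two polarities.
#' @return Signed `n_rows x n_cols` matrix (ON peak map minus OFF peak map).
#' @export
simple_rf <- function(on_stack, off_stack) {
  if (is.null(on_stack) || is.null(off_stack))
    stop("both ON and OFF kernel stacks are required for a signed RF")
  stopifnot(inherits(on_stack, "kernel_stack"), inherits(off_stack, "kernel_stack"))
  on_stack$peak_map - off_stack$peak_map
}

#' @export
print.kernel_stack <- function(x, ...) {
  cat(sprintf("%s kernel stack, cell %s: %d delays, peak at t = %d (S = %.3g)%s\n",
              x$polarity, x$cell_id, dim(x$maps)[1], x$peak_delay,
              max(x$norm_curve), if (x$degenerate) " [degenerate baseline]" else ""))
  invisible(x)
}

#' @export
plot.kernel_stack <- function(x, grid = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(x$peak_map), main = sprintf("%s peak map (t = %d)",
                                                x$polarity, x$peak_delay),
                  xlab = "azimuth", ylab = "elevation", useRaster = TRUE, ...)
  graphics::plot(seq_along(x$norm_curve) - 1L, x$norm_curve, type = "b",
                 xlab = "delay (frames)", ylab = "S(t)", main = "norm curve")
  graphics::abline(h = 5, lty = 2)
  invisible(x)
}
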