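#' Generate a ternary sparse-noise stimulus ensemble
#'
#' Each flashed image sets every tile of the grid independently to bright
#' (`+1`, probability `p_bright`), dark (`-1`, probability `p_dark`) or gray
#' (`0`, remaining probability). Images are flashed for `flash_ms`
#' milliseconds at `presentation_rate` per second; the ensemble stores one
#' frame per flashed image (the flash is collapsed to its onset microscope
#' frame, since response kernels are indexed by delay from onset) together
#' with the microscope frame index of each onset.
#'
#' Defaults reproduce the standard protocol: 10 percent bright, 10 percent
#' dark, 80 percent gray per tile, 166 ms flashes at 1 per second, microscope
#' frame rate 15.6 Hz; a 25-minute session yields 1500 presentations.
#'
#' @param n_stimuli number of flashed images.
#' @param grid a [stim_grid()].
#' @param p_bright,p_dark per-tile probabilities; `p_bright + p_dark <= 1`.
#' @param frame_rate microscope frame rate in Hz.
#' @param presentation_rate flashes per second.
#' @param flash_ms flash duration in milliseconds (metadata only).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `sparse_noise_stimulus`: list with `frames`
#'   (`n_stimuli x n_rows x n_cols` array over `{-1, 0, 1}`),
#'   `onset_frame_index` (1-based microscope frame of each onset), `grid`,
#'   `frame_rate`, `presentation_rate`, `flash_ms`, `p_bright`, `p_dark`,
#'   `n_frames` (total microscope frames covering the session).
#' @examples
#' s <- make_stimulus(100, seed = 1)
#' mean(s$frames == 1)  # close to 0.1
#' @export
make_stimulus <- function(n_stimuli = 1500, grid = stim_grid(),
                          p_bright = 0.1, p_dark = 0.1,
                          frame_rate = 15.6, presentation_rate = 1,
                          flash_ms = 166, seed = NULL) {
  stopifnot(inherits(grid, "stim_grid"), n_stimuli >= 1)
  if (p_bright < 0 || p_dark < 0 || p_bright + p_dark > 1)
    stop("need p_bright >= 0, p_dark >= 0 and p_bright + p_dark <= 1")
  if (!is.null(seed)) set.seed(seed)
  vals <- sample(c(1L, -1L, 0L), n_stimuli * grid$n_rows * grid$n_cols,
                 replace = TRUE,
                 prob = c(p_bright, p_dark, 1 - p_bright - p_dark))
  frames <- array(vals, dim = c(n_stimuli, grid$n_rows, grid$n_cols))
  spacing <- round(frame_rate / presentation_rate)
  onsets <- 1L + (seq_len(n_stimuli) - 1L) * as.integer(spacing)
  structure(
    list(frames = frames, onset_frame_index = onsets, grid = grid,
         frame_rate = frame_rate, presentation_rate = presentation_rate,
         flash_ms = flash_ms, p_bright = p_bright, p_dark = p_dark,
         n_frames = max(onsets) + as.integer(spacing)),
    class = "sparse_noise_stimulus"
  )
}

#' @export
print.sparse_noise_stimulus <- function(x, ...) {
  cat(sprintf(
    "Sparse-noise ensemble: %d images on a %d x %d grid (P+ %.2g, P- %.2g)\n",
    dim(x$frames)[1], x$grid$n_rows, x$grid$n_cols, x$p_bright, x$p_dark))
  cat(sprintf("  %g Hz microscope, %g flashes/s, %g ms flash, %d frames\n",
              x$frame_rate, x$presentation_rate, x$flash_ms, x$n_frames))
  invisible(x)
}

#' Simulate deconvolved activity of a population under a stimulus
#'
#' Linear-nonlinear Poisson front end. For each flashed image the stimulus
#' drive of a cell is the positive part of the inner product of its
#' ground-truth ON map with the bright tiles plus its OFF map with the dark
#' tiles; complex cells sum the two rectified subunit drives instead. Event
#' counts are drawn as `Poisson(baseline + gain * drive)` and placed
#' `delay_frames` microscope frames after stimulus onset (optionally
#' jittered); all other frames carry `Poisson(baseline)` background, with
#' optional zero-truncated Gaussian readout noise added on top. The output
#' stands in for deconvolved calcium event rates.
#'
#' @param population a [sample_population()] object.
#' @param stimulus a [make_stimulus()] ensemble on the same grid.
#' @param gain response gain (events per unit drive), >= 0.
#' @param baseline background event rate per frame, >= 0.
#' @param delay_frames response latency in microscope frames (>= 0).
#' @param delay_jitter integer; each response is displaced by a uniform
#'   integer in `[-delay_jitter, delay_jitter]` frames.
#' @param readout_sd standard deviation of additive Gaussian readout noise
#'   (truncated at zero); 0 disables it.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `response_matrix`: list with `activity`
#'   (`n_cells x n_frames`, non-negative), `frame_rate`, `delay_frames`.
#' @export
simulate_responses <- function(population, stimulus, gain = 2, baseline = 0.12,
                               delay_frames = 5, delay_jitter = 0,
                               readout_sd = 0, seed = NULL) {
  stopifnot(inherits(population, "v1_population"),
            inherits(stimulus, "sparse_noise_stimulus"))
  if (delay_frames < 0) stop("'delay_frames' must be >= 0")
  if (gain < 0) stop("'gain' must be >= 0")
  g <- population$grid
  if (g$n_rows != stimulus$grid$n_rows || g$n_cols != stimulus$grid$n_cols)
    stop("population RF grid and stimulus grid shapes differ")
  if (!is.null(seed)) set.seed(seed)

  n_stim <- dim(stimulus$frames)[1]
  n_tiles <- g$n_rows * g$n_cols
  S <- matrix(stimulus$frames, n_stim, n_tiles)  # stimuli x tiles
  B <- (S == 1) * 1; D <- (S == -1) * 1
  n_cells <- nrow(population$cells)
  n_frames <- stimulus$n_frames + delay_frames + delay_jitter

  # drive matrix: cells x stimuli
  on_mat <- matrix(0, n_cells, n_tiles)
  off_mat <- matrix(0, n_cells, n_tiles)
  for (i in seq_len(n_cells)) {
    if (!is.null(population$maps[[i]]$on)) on_mat[i, ] <- as.numeric(population$maps[[i]]$on)
    if (!is.null(population$maps[[i]]$off)) off_mat[i, ] <- as.numeric(population$maps[[i]]$off)
  }
  drv_on <- on_mat %*% t(B)
  drv_off <- off_mat %*% t(D)
  cplx <- population$cells$class == "COMPLEX"
  drive <- pmax(drv_on + drv_off, 0)
  drive[cplx, ] <- pmax(drv_on[cplx, , drop = FALSE], 0) +
    pmax(drv_off[cplx, , drop = FALSE], 0)

  activity <- matrix(stats::rpois(n_cells * n_frames, baseline),
                     n_cells, n_frames)
  lag <- rep(delay_frames, n_stim)
  if (delay_jitter > 0)
    lag <- lag + sample(seq(-delay_jitter, delay_jitter), n_stim, replace = TRUE)
  cols <- stimulus$onset_frame_index + lag
  evoked <- matrix(stats::rpois(length(drive), gain * drive), n_cells, n_stim)
  activity[, cols] <- activity[, cols] + evoked
  if (readout_sd > 0)
    activity <- pmax(activity + stats::rnorm(length(activity), 0, readout_sd), 0)

  structure(list(activity = activity, frame_rate = stimulus$frame_rate,
                 delay_frames = delay_frames),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Deconvolved activity: %d cells x %d frames at %g Hz (mean %.3g)\n",
              nrow(x$activity), ncol(x$activity), x$frame_rate,
              mean(x$activity)))
  invisible(x)
}
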