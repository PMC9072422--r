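# Shared fixture builders; everything is generated in code at test time.

quick_population <- function(seed, n_on = 60, n_off = 120, n_simple = 20,
                             n_complex = 20, amplitude = 0.5, ...) {
  bias <- make_bias_field(amplitude = amplitude, seed = seed)
  sample_population(bias, retinotopy_model(), n_on, n_off, n_simple,
                    n_complex, seed = seed + 1, ...)
}

# tiny end-to-end chunk: population + stimulus + responses + kernels
quick_kernels <- function(seed, n_stimuli = 1500, gain = 2, baseline = 0.12,
                          ...) {
  pop <- quick_population(seed, ...)
  stim <- make_stimulus(n_stimuli, seed = seed + 2)
  resp <- simulate_responses(pop, stim, gain = gain, baseline = baseline,
                             seed = seed + 3)
  list(pop = pop, stim = stim, resp = resp,
       kern = suppressWarnings(estimate_kernels(resp, stim)))
}

# brute-force event-triggered average: plain loops, no vectorization
brute_force_kernels <- function(activity, stimulus, cell, max_delay) {
  g <- stimulus$grid
  out <- list()
  for (pol in c("on", "off")) {
    want <- if (pol == "on") 1L else -1L
    maps <- array(0, dim = c(max_delay + 1, g$n_rows, g$n_cols))
    for (t in 0:max_delay) {
      for (i in seq_len(g$n_rows)) {
        for (j in seq_len(g$n_cols)) {
          acc <- c()
          for (s in seq_len(dim(stimulus$frames)[1])) {
            if (stimulus$frames[s, i, j] == want) {
              acc <- c(acc, activity[cell, stimulus$onset_frame_index[s] + t])
            }
          }
          maps[t + 1, i, j] <- if (length(acc)) mean(acc) else 0
        }
      }
    }
    out[[pol]] <- maps
  }
  out
}

# brute-force KDE: per-node double loop
brute_force_kde <- function(points, sigma, grid) {
  v <- matrix(0, length(grid$y), length(grid$x))
  for (iy in seq_along(grid$y)) {
    for (ix in seq_along(grid$x)) {
      s <- 0
      for (p in seq_len(nrow(points))) {
        d2 <- (grid$x[ix] - points[p, 1])^2 + (grid$y[iy] - points[p, 2])^2
        s <- s + exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
      }
      v[iy, ix] <- s / nrow(points)
    }
  }
  v
}

# two-sample energy-distance permutation test (returns p-value)
energy_perm_test <- function(a, b, n_perm = 99) {
  estat <- function(x, y) {
    dxy <- mean(sqrt(outer(x[, 1], y[, 1], `-`)^2 +
                       outer(x[, 2], y[, 2], `-`)^2))
    dxx <- mean(sqrt(outer(x[, 1], x[, 1], `-`)^2 +
                       outer(x[, 2], x[, 2], `-`)^2))
    dyy <- mean(sqrt(outer(y[, 1], y[, 1], `-`)^2 +
                       outer(y[, 2], y[, 2], `-`)^2))
    2 * dxy - dxx - dyy
  }
  obs <- estat(a, b)
  pooled <- rbind(a, b)
  n <- nrow(a)
  null <- replicate(n_perm, {
    idx <- sample.int(nrow(pooled))
    estat(pooled[idx[seq_len(n)], , drop = FALSE],
          pooled[idx[-seq_len(n)], , drop = FALSE])
  })
  (1 + sum(null >= obs)) / (n_perm + 1)
}
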