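#' Population composition from per-dataset class counts
#'
#' Pools ON, OFF and dual-polarity (ON+OFF) cell counts across datasets and
#' reports fractions (rounded to whole percent) plus the simple/complex
#' split within dual cells. Accepts either a per-dataset count table (columns
#' `n_on`, `n_off`, `n_dual` and optionally `n_simple`, `n_complex`) or a
#' per-cell classification table with a `class` column.
#'
#' @param x data frame of counts or a [classify_population()] table.
#' @return Object of class `composition_summary`: list with `counts`
#'   (`on`, `off`, `dual`, `simple`, `complex`, `total`), `percent`
#'   (on/off/dual, whole percent), `dual_split_percent` (simple/complex
#'   within dual, one decimal).
#' @export
population_composition <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) > 0)
  if ("class" %in% names(x) && !"n_on" %in% names(x)) {
    counts <- c(on = sum(x$class == "ON"), off = sum(x$class == "OFF"),
                simple = sum(x$class == "SIMPLE"),
                complex = sum(x$class == "COMPLEX"))
    counts <- c(counts, dual = unname(counts["simple"] + counts["complex"]))
  } else {
    need <- c("n_on", "n_off", "n_dual")
    if (!all(need %in% names(x))) stop("count table needs columns n_on, n_off, n_dual")
    if (any(unlist(x[need]) < 0)) stop("counts must be non-negative")
    counts <- c(on = sum(x$n_on), off = sum(x$n_off), dual = sum(x$n_dual),
                simple = if ("n_simple" %in% names(x)) sum(x$n_simple) else NA,
                complex = if ("n_complex" %in% names(x)) sum(x$n_complex) else NA)
  }
  total <- counts[["on"]] + counts[["off"]] + counts[["dual"]]
  pct <- round(100 * c(on = counts[["on"]], off = counts[["off"]],
                       dual = counts[["dual"]]) / total)
  split <- if (is.finite(counts[["simple"]]) && counts[["dual"]] > 0)
    round(100 * c(simple = counts[["simple"]], complex = counts[["complex"]]) /
            counts[["dual"]], 1)
  else c(simple = NA_real_, complex = NA_real_)
  structure(list(counts = c(counts, total = total), percent = pct,
                 dual_split_percent = split),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("Population composition (n = %d):\n", x$counts[["total"]]))
  cat(sprintf("  ON %d (%d%%), OFF %d (%d%%), ON+OFF %d (%d%%)\n",
              x$counts[["on"]], x$percent[["on"]], x$counts[["off"]],
              x$percent[["off"]], x$counts[["dual"]], x$percent[["dual"]]))
  if (is.finite(x$dual_split_percent[["simple"]]))
    cat(sprintf("  within ON+OFF: %.1f%% simple, %.1f%% complex\n",
                x$dual_split_percent[["simple"]],
                x$dual_split_percent[["complex"]]))
  invisible(x)
}

#' Compare mean simple-cell RF with the ON minus OFF mean
#'
#' Computes the mean peak-delay ON map over mono-contrast ON cells
#' (`mu_on`), the mean OFF map over OFF cells (`mu_off`), and the mean
#' signed receptive field over simple cells (`mu_s`), and correlates
#' `mu_on - mu_off` with `mu_s` across map entries. Under the biased-input
#' account the two agree. The p-value recomputes the correlation under
#' `n_perm` random reassignments of the cells' maps to the three groups
#' (group sizes fixed); reported as the fraction of permutations with
#' `|r| >= |r_obs|`.
#'
#' @param on_maps,off_maps,simple_rfs lists of matrices on a shared grid:
#'   peak ON maps of ON cells, peak OFF maps of OFF cells, and signed
#'   ON-OFF receptive fields of simple cells.
#' @param n_perm permutations for the null.
#' @param seed integer seed; `NULL` leaves the RNG alone.
#' @return Object of class `mean_rf_summary`: list with `mu_on`, `mu_off`,
#'   `mu_s`, `r_mean`, `p_value`, group sizes `n`.
#' @export
mean_rf_comparison <- function(on_maps, off_maps, simple_rfs,
                               n_perm = 1000, seed = NULL) {
  if (!length(on_maps) || !length(off_maps) || !length(simple_rfs))
    stop("need at least one map per group (ON, OFF, simple)")
  if (!is.null(seed)) set.seed(seed)
  avg <- function(l) Reduce(`+`, l) / length(l)
  mu_on <- avg(on_maps); mu_off <- avg(off_maps); mu_s <- avg(simple_rfs)
  r_obs <- stats::cor(as.numeric(mu_on - mu_off), as.numeric(mu_s))
  pool <- c(on_maps, off_maps, simple_rfs)
  sizes <- c(length(on_maps), length(off_maps), length(simple_rfs))
  r_null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool))
    g1 <- pool[idx[seq_len(sizes[1])]]
    g2 <- pool[idx[sizes[1] + seq_len(sizes[2])]]
    g3 <- pool[idx[sizes[1] + sizes[2] + seq_len(sizes[3])]]
    stats::cor(as.numeric(avg(g1) - avg(g2)), as.numeric(avg(g3)))
  }, numeric(1))
  structure(list(mu_on = mu_on, mu_off = mu_off, mu_s = mu_s,
                 r_mean = r_obs,
                 p_value = (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1),
                 n = stats::setNames(sizes, c("on", "off", "simple"))),
            class = "mean_rf_summary")
}

#' @export
print.mean_rf_summary <- function(x, ...) {
  cat(sprintf(
    "Mean-RF comparison: r(mu_on - mu_off, mu_s) = %.3f (p = %.4g; n = %d/%d/%d)\n",
    x$r_mean, x$p_value, x$n[1], x$n[2], x$n[3]))
  invisible(x)
}

#' Diversity of simple-cell receptive fields
#'
#' Correlates each simple cell's receptive field with the population mean
#' `mu_s` and tests whether the distribution of correlations is centered
#' above zero (two-sided one-sample sign-rank test). Cells with constant
#' maps are excluded and counted.
#'
#' @param simple_rfs list of signed receptive-field matrices.
#' @param mu_s mean simple-cell receptive field (matrix).
#' @return List with `r` (per-cell correlations), `p_value` (sign-rank),
#'   `mean_r`, `range`, `n_excluded`.
#' @export
rf_diversity <- function(simple_rfs, mu_s) {
  if (length(simple_rfs) < 2) stop("need at least 2 simple cells")
  r <- vapply(simple_rfs, function(m) {
    if (stats::sd(as.numeric(m)) == 0) NA_real_
    else stats::cor(as.numeric(m), as.numeric(mu_s))
  }, numeric(1))
  n_excl <- sum(is.na(r))
  r <- r[!is.na(r)]
  p <- if (length(r) >= 2 && any(r != 0))
    stats::wilcox.test(r, mu = 0, exact = FALSE)$p.value else NA_real_
  list(r = r, p_value = p, mean_r = mean(r), range = range(r),
       n_excluded = n_excl)
}

#' Nearest mono-contrast neighbors of a target cell
#'
#' Selects the `k` nearest ON and the `k` nearest OFF mono-contrast cells by
#' Euclidean distance in 3-D cortical coordinates (um), ties broken by cell
#' id; `k` applies per polarity. A 2-D (depth-projected) distance is
#' available behind `use_depth = FALSE`.
#'
#' @param target numeric length-3 cortical position of the target cell (um).
#' @param mono_cells data frame with `id`, `class` ("ON"/"OFF"), `x1`, `x2`,
#'   `x3`.
#' @param k neighbors per polarity.
#' @param use_depth include `x3` in the distance (default TRUE).
#' @return List with data frames `on` and `off` (`id`, `distance`), each of
#'   `k` rows sorted by distance.
#' @export
knn_neighbors <- function(target, mono_cells, k, use_depth = TRUE) {
  stopifnot(length(target) == 3, k >= 1)
  sel <- function(pol) {
    m <- mono_cells[mono_cells$class == pol, , drop = FALSE]
    if (nrow(m) < k)
      stop(sprintf("only %d mono-contrast %s cells available but k = %d",
                   nrow(m), pol, k))
    d <- sqrt((m$x1 - target[1])^2 + (m$x2 - target[2])^2 +
                if (use_depth) (m$x3 - target[3])^2 else 0)
    ord <- order(d, m$id)[seq_len(k)]
    data.frame(id = m$id[ord], distance = d[ord])
  }
  list(on = sel("ON"), off = sel("OFF"))
}

#' Non-negative decomposition of a simple-cell receptive field
#'
#' Models a simple cell's signed receptive field as a non-negative linear
#' combination of its neighbors' receptive fields. ON neighbor maps enter
#' the design with a positive sign and OFF maps with a negative sign, so
#' non-negative weights assemble an ON-minus-OFF field. Solved by
#' Lawson-Hanson active-set NNLS.
#'
#' @param target_rf signed receptive-field matrix of the target cell.
#' @param on_maps,off_maps lists of neighbor maps (matrices on the same
#'   grid), ordered as returned by [knn_neighbors()].
#' @param on_ids,off_ids optional neighbor ids (stored in the result).
#' @param on_distances,off_distances optional neighbor distances (um).
#' @return Object of class `neighborhood_fit`: list with `weights_on`,
#'   `weights_off` (non-negative), `fit_corr` (Pearson r between model and
#'   target, `NA` for an all-zero target), `fitted`, `normalized_weights`
#'   (per polarity, sorted descending, summing to 1 when any weight is
#'   positive), `n90` (per polarity: smallest number of neighbors holding
#'   at least 90 percent of that polarity's weight), `ids`, `distances`,
#'   `k`.
#' @export
nnls_fit <- function(target_rf, on_maps, off_maps,
                     on_ids = NULL, off_ids = NULL,
                     on_distances = NULL, off_distances = NULL) {
  if (!length(on_maps) && !length(off_maps)) stop("need at least one neighbor map")
  dims <- dim(target_rf)
  for (m in c(on_maps, off_maps))
    if (!identical(dim(m), dims)) stop("neighbor maps must share the target grid shape")
  Phi <- cbind(
    if (length(on_maps)) sapply(on_maps, as.numeric) else NULL,
    if (length(off_maps)) -sapply(off_maps, as.numeric) else NULL)
  Phi <- matrix(Phi, nrow = prod(dims))
  y <- as.numeric(target_rf)
  n_on <- length(on_maps); n_off <- length(off_maps)
  if (all(y == 0)) {
    w <- rep(0, n_on + n_off)
  } else {
    w <- as.numeric(pracma::lsqnonneg(Phi, y)$x)
  }
  fitted <- as.numeric(Phi %*% w)
  fit_corr <- if (all(y == 0) || stats::sd(fitted) == 0) NA_real_
              else stats::cor(fitted, y)
  w_on <- w[seq_len(n_on)]; w_off <- w[n_on + seq_len(n_off)]
  norm_sorted <- function(v) {
    if (sum(v) == 0) return(rep(0, length(v)))
    sort(v / sum(v), decreasing = TRUE)
  }
  n90 <- function(v) {
    ns <- norm_sorted(v)
    if (sum(ns) == 0) return(NA_integer_)
    as.integer(which(cumsum(ns) >= 0.9)[1])
  }
  structure(
    list(weights_on = w_on, weights_off = w_off,
         fit_corr = fit_corr,
         fitted = matrix(fitted, dims[1], dims[2]),
         normalized_weights = list(on = norm_sorted(w_on),
                                   off = norm_sorted(w_off)),
         n90 = c(on = n90(w_on), off = n90(w_off)),
         ids = list(on = on_ids, off = off_ids),
         distances = list(on = on_distances, off = off_distances),
         k = max(n_on, n_off)),
    class = "neighborhood_fit"
  )
}

#' @export
print.neighborhood_fit <- function(x, ...) {
  cat(sprintf(
    "Neighborhood NNLS fit (k = %d): r = %.3f; n90 ON = %s, OFF = %s\n",
    x$k, x$fit_corr, x$n90[["on"]], x$n90[["off"]]))
  invisible(x)
}

#' Fit the neighborhood model to every simple cell
#'
#' Convenience wrapper: for each simple cell, selects `k` ON and `k` OFF
#' mono-contrast neighbors with [knn_neighbors()] and decomposes its signed
#' receptive field with [nnls_fit()].
#'
#' @param simple_cells data frame with `id`, `x1`, `x2`, `x3` of simple
#'   cells.
#' @param simple_rfs list of signed RF matrices, parallel to `simple_cells`.
#' @param mono_cells data frame of mono-contrast cells (`id`, `class`,
#'   `x1`, `x2`, `x3`).
#' @param mono_maps named list (by cell id) of mono-contrast peak maps.
#' @param k neighbors per polarity.
#' @param use_depth see [knn_neighbors()].
#' @return List of `neighborhood_fit` objects.
#' @export
fit_neighborhood_model <- function(simple_cells, simple_rfs, mono_cells,
                                   mono_maps, k = 5, use_depth = TRUE) {
  stopifnot(nrow(simple_cells) == length(simple_rfs))
  lapply(seq_len(nrow(simple_cells)), function(i) {
    nb <- knn_neighbors(as.numeric(simple_cells[i, c("x1", "x2", "x3")]),
                        mono_cells, k, use_depth)
    nnls_fit(simple_rfs[[i]],
             on_maps = mono_maps[as.character(nb$on$id)],
             off_maps = mono_maps[as.character(nb$off$id)],
             on_ids = nb$on$id, off_ids = nb$off$id,
             on_distances = nb$on$distance, off_distances = nb$off$distance)
  })
}

#' Goodness of fit of the neighborhood model across k
#'
#' Runs the non-negative neighborhood model for each neighborhood size in
#' `k_range` and summarizes the distribution of fit correlations, reporting
#' the smallest `k` whose median is within `epsilon` of the best median over
#' the range (the saturation point; performance typically saturates around
#' k of 5).
#'
#' @inheritParams fit_neighborhood_model
#' @param k_range integer vector of neighborhood sizes.
#' @param epsilon saturation tolerance in correlation units.
#' @return List with `summary` (data frame: `k`, `median`, `q25`, `q75`),
#'   `k_saturation`, and `fit_corr` (matrix cells x k).
#' @export
sweep_k <- function(simple_cells, simple_rfs, mono_cells, mono_maps,
                    k_range = 1:8, epsilon = 0.02, use_depth = TRUE) {
  if (!length(k_range)) stop("k_range must be non-empty")
  fc <- sapply(k_range, function(k) {
    fits <- fit_neighborhood_model(simple_cells, simple_rfs, mono_cells,
                                   mono_maps, k, use_depth)
    vapply(fits, function(f) f$fit_corr, numeric(1))
  })
  fc <- matrix(fc, nrow = length(simple_rfs))
  med <- apply(fc, 2, stats::median, na.rm = TRUE)
  s <- data.frame(k = k_range, median = med,
                  q25 = apply(fc, 2, stats::quantile, 0.25, na.rm = TRUE),
                  q75 = apply(fc, 2, stats::quantile, 0.75, na.rm = TRUE))
  list(summary = s,
       k_saturation = k_range[which(med >= max(med) - epsilon)[1]],
       fit_corr = fc)
}

#' Sparsity of neighborhood weights
#'
#' Pools fits and reports, per polarity, the mean normalized weight by rank,
#' the mean cumulative weight curve, and the distribution of `n90` (the
#' number of neighbors needed for 90 percent of the weight). Fits with zero
#' total weight in a polarity are excluded from that polarity's curves.
#'
#' @param fits list of [nnls_fit()] results.
#' @return List with per-polarity `mean_weights`, `cumulative`, `n90`
#'   vectors and `n_excluded`.
#' @export
weight_sparsity <- function(fits) {
  if (!length(fits)) stop("need at least one fit")
  out <- list()
  for (pol in c("on", "off")) {
    W <- lapply(fits, function(f) f$normalized_weights[[pol]])
    keep <- vapply(W, function(w) sum(w) > 0, logical(1))
    if (!any(keep)) {
      out[[pol]] <- list(mean_weights = numeric(0), cumulative = numeric(0),
                         n90 = integer(0), n_excluded = sum(!keep))
      next
    }
    kmax <- max(vapply(W[keep], length, integer(1)))
    M <- t(vapply(W[keep], function(w) c(w, rep(0, kmax - length(w))),
                  numeric(kmax)))
    M <- matrix(M, ncol = kmax)
    mw <- colMeans(M)
    out[[pol]] <- list(mean_weights = mw, cumulative = cumsum(mw) / sum(mw),
                       n90 = vapply(fits[keep], function(f) f$n90[[pol]],
                                    integer(1)),
                       n_excluded = sum(!keep))
  }
  out
}

#' Compare distances of selected ON vs OFF neighbors
#'
#' Pools the neighbor distances used by the fits and compares ON against
#' OFF with a two-sided rank-sum test. When ON cells are sparser than OFF
#' cells (as in mouse V1, roughly 27 vs 55 percent), selected ON neighbors
#' sit statistically farther from the target cell. Distances can be
#' restricted to neighbors that received positive weight.
#'
#' @param fits list of [nnls_fit()] results carrying distances.
#' @param positive_only use only neighbors with weight > 0.
#' @return List with `d_on`, `d_off` (pooled distances, um), `p_value`
#'   (rank-sum; `NA` when degenerate), `median_on`, `median_off`.
#' @export
neighbor_distance_comparison <- function(fits, positive_only = FALSE) {
  if (length(fits) < 10) stop("need at least 10 fits")
  get_d <- function(f, pol) {
    d <- f$distances[[pol]]
    if (is.null(d)) return(numeric(0))
    if (positive_only) d <- d[f[[paste0("weights_", pol)]] > 0]
    d
  }
  d_on <- unlist(lapply(fits, get_d, "on"))
  d_off <- unlist(lapply(fits, get_d, "off"))
  p <- if (length(d_on) && length(d_off) &&
           (stats::sd(c(d_on, d_off)) > 0))
    stats::wilcox.test(d_on, d_off, exact = FALSE)$p.value
  else NA_real_
  list(d_on = d_on, d_off = d_off, p_value = p,
       median_on = stats::median(d_on), median_off = stats::median(d_off))
}
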