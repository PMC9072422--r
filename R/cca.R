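#' Align cortical and visual coordinates by canonical correlation analysis
#'
#' Finds centering vectors and projection matrices `A` (3 x 2, cortical to
#' canonical) and `B` (2 x 2, visual to canonical) such that, with the
#' row-vector convention `xhat = (x - xbar) %*% A` and
#' `yhat = (y - ybar) %*% B`, the matching canonical coordinate pairs
#' `(xhat1, yhat1)` and `(xhat2, yhat2)` are maximally correlated, the
#' cross pairs are uncorrelated, and every canonical variable has unit
#' sample variance. Including cortical depth lets the first projection
#' compensate for small tilts of the objective relative to the cortical
#' surface normal. Solved by SVD of the whitened cross-covariance; the sign
#' convention makes each canonical correlation non-negative and the
#' projections deterministic for a given input.
#'
#' @param cortical_xyz `n x 3` matrix of cortical positions (um).
#' @param visual_yy `n x 2` matrix of receptive-field centers (deg), rows
#'   matching `cortical_xyz`.
#' @return Object of class `cca_model`: list with `mean_x`, `mean_y`, `A`,
#'   `B`, `rho` (`rho1 >= rho2 >= 0`), `n_cells`.
#' @examples
#' set.seed(1)
#' x <- cbind(matrix(rnorm(200), 100, 2), rnorm(100))
#' m <- fit_cca(x, x[, 1:2] + matrix(rnorm(200, 0, 0.3), 100, 2))
#' m$rho
#' @export
fit_cca <- function(cortical_xyz, visual_yy) {
  X <- as.matrix(cortical_xyz); Y <- as.matrix(visual_yy)
  stopifnot(ncol(X) == 3, ncol(Y) == 2, nrow(X) == nrow(Y))
  n <- nrow(X)
  if (n < 10) stop("need at least 10 cells with both coordinates")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  for (nm in list(list(Sxx, colnames(X), "cortical"),
                  list(Syy, colnames(Y), "visual"))) {
    ev <- eigen(nm[[1]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev)) {
      culprit <- which.min(diag(nm[[1]]))
      stop(sprintf("rank-deficient %s coordinates (column %d is degenerate)",
                   nm[[3]], culprit))
    }
  }
  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
  }
  Wx <- inv_sqrt(Sxx); Wy <- inv_sqrt(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy)
  A <- Wx %*% sv$u[, 1:2, drop = FALSE]
  B <- Wy %*% sv$v[, 1:2, drop = FALSE]
  rho <- sv$d[1:2]
  # deterministic sign: largest-magnitude loading of each cortical projection
  # positive; flip the visual side jointly so rho stays >= 0
  for (k in 1:2) {
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) { A[, k] <- -A[, k]; B[, k] <- -B[, k] }
  }
  structure(list(mean_x = mx, mean_y = my, A = A, B = B, rho = rho,
                 n_cells = n),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("CCA alignment (n = %d): rho1 = %.4f, rho2 = %.4f\n",
              x$n_cells, x$rho[1], x$rho[2]))
  invisible(x)
}

#' Project coordinates into canonical space
#'
#' @param points `n x 3` cortical (um) or `n x 2` visual (deg) coordinates.
#' @param model a [fit_cca()] model.
#' @param which `"cortical"` or `"visual"`.
#' @return `n x 2` matrix of canonical coordinates; on the fitting data each
#'   column has unit sample variance.
#' @export
cca_transform <- function(points, model, which = c("cortical", "visual")) {
  which <- match.arg(which)
  stopifnot(inherits(model, "cca_model"))
  P <- matrix(as.numeric(as.matrix(points)), ncol = if (which == "cortical") 3 else 2)
  if (which == "cortical") {
    if (ncol(P) != 3) stop("cortical points must have 3 columns")
    sweep(P, 2, model$mean_x) %*% model$A
  } else {
    if (ncol(P) != 2) stop("visual points must have 2 columns")
    sweep(P, 2, model$mean_y) %*% model$B
  }
}

#' Correlation between cortical and visual canonical fluctuation maps
#'
#' The biased-input account predicts that the ON-OFF density fluctuation in
#' canonical cortical space mirrors the fluctuation of ON/OFF
#' receptive-field centers in canonical visual space. This function
#' correlates the two maps over grid nodes and derives a p-value from a
#' joint label-shuffle null: each shuffle permutes the ON/OFF labels over
#' cells (every cell keeps its cortical and visual coordinates), recomputes
#' both canonical fluctuation maps, and records their correlation;
#' `p = (1 + #{|r_null| >= |r_obs|}) / (n_shuffles + 1)`.
#'
#' @param cortical_canonical `n x 2` canonical cortical coordinates.
#' @param visual_canonical `n x 2` canonical visual coordinates (same cells).
#' @param labels logical or character vector: `TRUE`/"ON" for ON cells.
#' @param sigma canonical density bandwidth (default 0.25).
#' @param grid a [density_grid()]; default [canonical_grid()].
#' @param n_shuffles shuffle count.
#' @param seed integer seed; `NULL` leaves the RNG alone.
#' @return List with `pearson_r`, `p_value`, and the observed value matrices
#'   `map_cortical`, `map_visual`.
#' @export
map_correlation <- function(cortical_canonical, visual_canonical, labels,
                            sigma = 0.25, grid = canonical_grid(),
                            n_shuffles = 1000, seed = NULL) {
  Xc <- as.matrix(cortical_canonical); Yc <- as.matrix(visual_canonical)
  lab <- if (is.character(labels)) labels == "ON" else as.logical(labels)
  stopifnot(nrow(Xc) == nrow(Yc), length(lab) == nrow(Xc))
  n_on <- sum(lab); n_off <- sum(!lab)
  if (n_on == 0 || n_off == 0) stop("need both ON and OFF cells")
  if (!is.null(seed)) set.seed(seed)
  Kx <- kde_kernel_matrix(Xc, sigma, grid)
  Ky <- kde_kernel_matrix(Yc, sigma, grid)
  wvec <- function(l) ifelse(l, 1 / sum(l), -1 / sum(!l))
  vx <- as.numeric(Kx %*% wvec(lab)); vy <- as.numeric(Ky %*% wvec(lab))
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0)
    stop("constant fluctuation map; correlation undefined")
  r_obs <- stats::cor(vx, vy)
  n <- length(lab)
  r_null <- vapply(seq_len(n_shuffles), function(s) {
    l <- logical(n); l[sample.int(n, n_on)] <- TRUE
    w <- wvec(l)
    stats::cor(as.numeric(Kx %*% w), as.numeric(Ky %*% w))
  }, numeric(1))
  to_m <- function(v) matrix(v, length(grid$y), length(grid$x), byrow = TRUE)
  list(pearson_r = r_obs,
       p_value = (1 + sum(abs(r_null) >= abs(r_obs))) / (n_shuffles + 1),
       map_cortical = to_m(vx), map_visual = to_m(vy))
}

#' Per-polarity canonical correlations and OFF vs ON comparison
#'
#' Fits CCA separately to the ON-only and OFF-only mono-contrast cells of
#' each dataset and compares the resulting canonical correlations across
#' datasets with a paired two-sided sign-rank test (first canonical pair;
#' both pairs are returned). Larger retinotopic scatter of ON cells
#' predicts lower ON canonical correlations.
#'
#' @param datasets a list of data frames, each with columns `x1`, `x2`, `x3`
#'   (um), `y1`, `y2` (deg) and `class` ("ON"/"OFF").
#' @param min_cells minimum cells per polarity; datasets below it are
#'   excluded (recorded in the output).
#' @return List with `per_dataset` (data frame: dataset, `rho1_on`,
#'   `rho2_on`, `rho1_off`, `rho2_off`), `p_value` (paired sign-rank on
#'   rho1, OFF vs ON), `excluded` (indices).
#' @export
polarity_cca_comparison <- function(datasets, min_cells = 10) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  rows <- list(); excluded <- integer(0)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    on <- d[d$class == "ON", , drop = FALSE]
    off <- d[d$class == "OFF", , drop = FALSE]
    if (nrow(on) < min_cells || nrow(off) < min_cells) {
      excluded <- c(excluded, i)
      next
    }
    m_on <- fit_cca(as.matrix(on[, c("x1", "x2", "x3")]),
                    as.matrix(on[, c("y1", "y2")]))
    m_off <- fit_cca(as.matrix(off[, c("x1", "x2", "x3")]),
                     as.matrix(off[, c("y1", "y2")]))
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = i, rho1_on = m_on$rho[1], rho2_on = m_on$rho[2],
      rho1_off = m_off$rho[1], rho2_off = m_off$rho[2])
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset = integer(0), rho1_on = numeric(0),
               rho2_on = numeric(0), rho1_off = numeric(0),
               rho2_off = numeric(0))
  p <- if (nrow(per) >= 2 && any(per$rho1_off != per$rho1_on))
    stats::wilcox.test(per$rho1_off, per$rho1_on, paired = TRUE,
                       exact = FALSE)$p.value
  else NA_real_
  list(per_dataset = per, p_value = p, excluded = excluded)
}
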