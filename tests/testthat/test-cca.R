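# brute-force CCA oracle: generalized eigenproblem on the covariance blocks
eigen_cca <- function(X, Y) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  sqrt(sort(Re(eigen(M)$values), decreasing = TRUE)[1:2])
}

test_that("a noiseless linear map yields canonical correlations of one", {
  set.seed(1)
  y <- cbind(runif(100, 0, 144), runif(100, 0, 64))
  # exact affine map to the surface plane; depth is unrelated to y
  x <- cbind(y %*% matrix(c(6, 0.5, -0.3, 8), 2), rnorm(100, 250, 60))
  m <- fit_cca(x, y)
  expect_lt(max(abs(m$rho - 1)), 1e-10)
})

test_that("canonical correlations match the generalized-eigenproblem oracle", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(300 * 3), 300)
    y <- x[, 1:2] + matrix(rnorm(600, 0, runif(1, 0.3, 2)), 300)
    m <- fit_cca(x, y)
    expect_lt(max(abs(m$rho - eigen_cca(x, y))), 1e-8)
    # and the base-R QR-based implementation agrees too
    cc <- stats::cancor(x, y)
    expect_lt(max(abs(m$rho - cc$cor)), 1e-8)
  }
})

test_that("canonical variates have unit variance and diagonal correlation", {
  set.seed(2)
  x <- matrix(rnorm(200 * 3), 200)
  y <- 0.8 * x[, 1:2] + matrix(rnorm(400, 0, 0.6), 200)
  m <- fit_cca(x, y)
  xh <- cca_transform(x, m, "cortical")
  yh <- cca_transform(y, m, "visual")
  expect_lt(max(abs(apply(xh, 2, var) - 1)), 1e-8)
  expect_lt(max(abs(apply(yh, 2, var) - 1)), 1e-8)
  expect_lt(abs(cor(xh[, 1], yh[, 2])), 1e-8)
  expect_lt(abs(cor(xh[, 2], yh[, 1])), 1e-8)
  expect_equal(c(cor(xh[, 1], yh[, 1]), cor(xh[, 2], yh[, 2])), m$rho,
               tolerance = 1e-10)
  expect_true(m$rho[1] >= m$rho[2] && m$rho[2] >= 0)
  # the mean point maps to the origin
  expect_equal(as.numeric(cca_transform(matrix(colMeans(x), 1), m, "cortical")),
               c(0, 0))
})

test_that("null canonical correlations stay below the permutation envelope", {
  hits <- sapply(1:40, function(s) {
    set.seed(s)
    x <- matrix(rnorm(500 * 3), 500)
    y <- matrix(rnorm(500 * 2), 500)
    rho1 <- fit_cca(x, y)$rho[1]
    perm <- sapply(1:100, function(i) fit_cca(x, y[sample.int(500), ])$rho[1])
    rho1 < max(perm)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("CCA is invariant to affine re-expression of the inputs", {
  set.seed(3)
  x <- matrix(rnorm(150 * 3), 150)
  y <- x[, 1:2] + matrix(rnorm(300, 0, 0.5), 150)
  m1 <- fit_cca(x, y)
  A <- matrix(c(2, 0.3, -1, 0.1, 1.5, 0.7, 0, -0.2, 3), 3)
  B <- matrix(c(0.5, 1.2, -0.8, 2), 2)
  m2 <- fit_cca(x %*% A + 5, y %*% B - 2)
  xh1 <- cca_transform(x, m1, "cortical")
  xh2 <- cca_transform(x %*% A + 5, m2, "cortical")
  for (k in 1:2) {
    agree <- min(max(abs(xh1[, k] - xh2[, k])), max(abs(xh1[, k] + xh2[, k])))
    expect_lt(agree, 1e-6)
  }
  expect_lt(max(abs(m1$rho - m2$rho)), 1e-8)
})

test_that("rank-deficient coordinates are rejected with a named column", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3); x[, 3] <- 1  # constant depth column
  y <- matrix(rnorm(40), 20, 2)
  expect_error(fit_cca(x, y), "cortical.*column 3|rank-deficient")
  expect_error(fit_cca(matrix(rnorm(27), 9, 3), matrix(rnorm(18), 9, 2)),
               "at least 10")
})

test_that("rho recovers the theoretical correlation of a noisy linear model", {
  # per-axis rho_true = s / sqrt(s^2 + sigma^2) for an isotropic scaled map
  set.seed(5)
  s_scale <- 2; sig <- 1.5
  rho_true <- s_scale / sqrt(s_scale^2 + sig^2)
  x <- matrix(rnorm(500 * 3), 500)
  y <- s_scale * x[, 1:2] + matrix(rnorm(1000, 0, sig), 500)
  m <- fit_cca(x, y)
  expect_lt(max(abs(m$rho - rho_true)), 0.05)
})

test_that("planted scatter difference reproduces the OFF > ON ordering", {
  run <- function(ratio, seeds) {
    sapply(seeds, function(s) {
      set.seed(s)
      datasets <- lapply(1:6, function(d) {
        y <- cbind(runif(120, 0, 144), runif(120, 0, 64))
        cls <- rep(c("ON", "OFF"), each = 60)
        sc <- ifelse(cls == "ON", 30 * ratio, 30)
        x12 <- retinotopy_map(retinotopy_model(), y[, 1], y[, 2]) +
          matrix(rnorm(240, 0, sc), 120)
        data.frame(x1 = x12[, 1], x2 = x12[, 2],
                   x3 = sample(seq(150, 360, 30), 120, TRUE),
                   y1 = y[, 1], y2 = y[, 2], class = cls)
      })
      res <- polarity_cca_comparison(datasets)
      c(off_gt_on = mean(res$per_dataset$rho1_off > res$per_dataset$rho1_on),
        p = res$p_value)
    })
  }
  planted <- run(2, 1:20)
  expect_gte(mean(planted["off_gt_on", ] > 0.5), 0.9)
  null <- run(1, 1:20)
  expect_gte(mean(null["p", ] > 0.05), 0.75)

  # zero scatter in both polarities: all canonical correlations are one
  set.seed(6)
  y <- cbind(runif(40, 0, 144), runif(40, 0, 64))
  x12 <- retinotopy_map(retinotopy_model(), y[, 1], y[, 2])
  d0 <- data.frame(x1 = x12[, 1], x2 = x12[, 2],
                   x3 = sample(seq(150, 360, 30), 40, TRUE),
                   y1 = y[, 1], y2 = y[, 2],
                   class = rep(c("ON", "OFF"), each = 20))
  res0 <- polarity_cca_comparison(d0)
  expect_lt(max(abs(unlist(res0$per_dataset[, -1]) - 1)), 1e-8)
})
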