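test_that("kde2d matches its definition and conserves mass", {
  g <- density_grid(c(-120, 120), c(-120, 120), 10)
  # single point at the center: field is the Gaussian kernel itself
  f <- kde2d(cbind(0, 0), 30, g)
  expect_equal(max(f$values), f$values[13, 13])
  expect_equal(f$values[13, 13], 1 / (2 * pi * 30^2))
  # two coincident points are indistinguishable from one
  f2 <- kde2d(rbind(c(0, 0), c(0, 0)), 30, g)
  expect_equal(f2$values, f$values)
  # 200 random points: brute-force per-node double-loop oracle
  set.seed(1)
  pts <- cbind(runif(200, -50, 50), runif(200, -50, 50))
  f3 <- kde2d(pts, 20, g)
  expect_lt(max(abs(f3$values - brute_force_kde(pts, 20, g))), 1e-12)
  # mass conservation on a >= 4-sigma padded grid
  expect_lt(abs(sum(f3$values) * 10^2 - 1), 0.05)
  expect_error(kde2d(matrix(0, 0, 2), 30, g), "empty")
})

test_that("null fluctuation maps flag about 2*alpha of nodes", {
  g <- density_grid(c(0, 900), c(0, 540), 30)
  frac <- sapply(1:50, function(s) {
    set.seed(s)
    pts <- cbind(runif(150, 0, 900), runif(150, 0, 540))
    fl <- fluctuation_map(pts[1:50, ], pts[51:150, ], 30, g,
                          n_shuffles = 200, alpha = 0.005, seed = s + 500)
    mean(fl$sig_pos | fl$sig_neg)
  })
  expect_lt(mean(frac), 3 * 2 * 0.005)
  expect_gt(mean(frac), 0.0005)  # not degenerate either
})

test_that("planted separation produces correctly signed domains", {
  set.seed(2)
  on <- cbind(rnorm(80, 300, 40), rnorm(80, 270, 40))
  off <- cbind(rnorm(120, 500, 40), rnorm(120, 270, 40))
  g <- density_grid(c(100, 700), c(100, 440), 10)
  fl <- fluctuation_map(on, off, 30, g, n_shuffles = 500, alpha = 0.002,
                        seed = 3)
  nodes <- expand.grid(x = g$x, y = g$y)
  pos_x <- mean(nodes$x[t(fl$sig_pos)])
  neg_x <- mean(nodes$x[t(fl$sig_neg)])
  expect_true(any(fl$sig_pos) && any(fl$sig_neg))
  expect_lt(pos_x, 400)  # ON-dominant mass sits at the ON cluster
  expect_gt(neg_x, 400)  # OFF-dominant mass at the OFF cluster

  # swapping inputs negates values and exchanges the masks
  fl2 <- fluctuation_map(off, on, 30, g, n_shuffles = 500, alpha = 0.002,
                         seed = 3)
  expect_equal(fl2$values, -fl$values)
  expect_equal(fl2$sig_pos, fl$sig_neg)
  expect_equal(fl2$sig_neg, fl$sig_pos)
})

test_that("alpha is clamped when shuffles cannot resolve it", {
  set.seed(4)
  on <- cbind(runif(20), runif(20)); off <- cbind(runif(20), runif(20))
  g <- density_grid(c(0, 1), c(0, 1), 0.2)
  expect_warning(
    fluctuation_map(on, off, 0.2, g, n_shuffles = 100, alpha = 0.001,
                    seed = 5),
    "clamping")
})

test_that("level sets recover block geometry and pixel counts", {
  g <- density_grid(c(0, 400), c(0, 300), 10)
  fl <- structure(list(
    sig_pos = matrix(FALSE, length(g$y), length(g$x)),
    sig_neg = matrix(FALSE, length(g$y), length(g$x)),
    grid = g), class = "fluctuation_map")
  expect_equal(nrow(extract_level_sets(fl)$domains), 0)

  fl$sig_pos[10:19, 15:24] <- TRUE   # 10 x 10 node block on a 10 um grid
  ds <- extract_level_sets(fl)
  on_rows <- ds$domains[ds$domains$polarity == "ON", ]
  expect_equal(nrow(on_rows), 1)
  expect_lt(abs(on_rows$area - 8100) / 8100, 0.15)  # contour at node centers
  # total area within one contour-width (perimeter x half-spacing) of
  # flagged-node count x node area
  perim <- 4 * 90
  expect_lt(abs(sum(on_rows$area) - 100 * 100), perim * 10 / 2 + 4 * 10^2)
  expect_gte(on_rows$n_nodes, 1)
})

test_that("split-half maps of one point pattern correlate perfectly", {
  set.seed(6)
  half <- data.frame(x1 = runif(60, 0, 900), x2 = runif(60, 0, 540),
                     class = rep(c("ON", "OFF"), each = 30))
  cells <- rbind(transform(half, x3 = 150), transform(half, x3 = 300))
  res <- split_half_columnarity(cells, 30, native_grid(30), n_shuffles = 50,
                                seed = 7)
  expect_equal(res$pearson_r, 1)
})

test_that("split-half p-values are calibrated under independent labels", {
  g <- density_grid(c(0, 900), c(0, 540), 45)
  ps <- sapply(1:50, function(s) {
    set.seed(s + 900)
    cells <- data.frame(x1 = runif(160, 0, 900), x2 = runif(160, 0, 540),
                        x3 = sample(c(150, 180, 210, 240), 160, TRUE),
                        class = sample(rep(c("ON", "OFF"), 80)))
    split_half_columnarity(cells, 30, g, n_shuffles = 99, seed = s)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("columnar populations give positive split-half correlation", {
  # classes are independent of depth by construction, so the planted ON/OFF
  # domains (strong bias field) should reappear in both depth halves
  hits <- sapply(1:20, function(s) {
    bias <- make_bias_field(amplitude = 0.8, seed = s + 300)
    pop <- sample_population(bias, retinotopy_model(), 270, 550, 0, 0,
                             seed = s + 301)
    res <- split_half_columnarity(pop$cells, 30, native_grid(30),
                                  n_shuffles = 199, seed = s)
    res$pearson_r > 0 && res$p_value < 0.01
  })
  expect_gte(mean(hits), 0.9)
})
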