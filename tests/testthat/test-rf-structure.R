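g8 <- stim_grid()

test_that("composition pools counts and rounds fractions", {
  tab <- data.frame(n_on = c(1), n_off = c(1), n_dual = c(2))
  cs <- population_composition(tab)
  expect_equal(unname(cs$percent), c(25, 25, 50))
  expect_error(population_composition(data.frame(n_on = -1, n_off = 1,
                                                 n_dual = 0)), "non-negative")
  # from a per-cell classification table
  cls <- data.frame(class = c("ON", "OFF", "OFF", "SIMPLE", "COMPLEX"))
  cs2 <- population_composition(cls)
  expect_equal(cs2$counts[["dual"]], 2)
  expect_equal(unname(cs2$percent), c(20, 40, 40))
})

test_that("mean-RF comparison is exact in the one-cell case and calibrated", {
  on <- gaussian_map(g8, 60, 30, 9)
  off <- gaussian_map(g8, 80, 30, 9)
  res <- mean_rf_comparison(list(on), list(off), list(on - off),
                            n_perm = 200, seed = 1)
  expect_equal(res$r_mean, 1)

  # generative self-consistency: simple RFs built from the mono pool
  set.seed(2)
  ons <- lapply(1:200, function(i)
    gaussian_map(g8, runif(1, 20, 124), runif(1, 10, 54), 9))
  offs <- lapply(1:200, function(i)
    gaussian_map(g8, runif(1, 20, 124), runif(1, 10, 54), 9))
  simples <- lapply(1:200, function(i)
    Reduce(`+`, ons[sample(200, 3)]) / 3 -
      Reduce(`+`, offs[sample(200, 3)]) / 3)
  res2 <- mean_rf_comparison(ons, offs, simples, n_perm = 200, seed = 3)
  expect_gt(res2$r_mean, 0.9)
  expect_lt(res2$p_value, 0.02)

  # fully exchangeable groups (all maps from one ensemble): p uniform
  ps <- sapply(1:40, function(s) {
    set.seed(s + 40)
    pool <- lapply(1:60, function(i)
      gaussian_map(g8, runif(1, 20, 124), runif(1, 10, 54), 9))
    mean_rf_comparison(pool[1:20], pool[21:40], pool[41:60],
                       n_perm = 99, seed = s)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_error(mean_rf_comparison(list(), list(on), list(on)), "at least one")
})

test_that("rf_diversity matches its degenerate cases", {
  mu <- gaussian_map(g8, 60, 30, 9) - gaussian_map(g8, 80, 30, 9)
  all_same <- rf_diversity(list(mu, mu, mu), mu)
  expect_true(all(all_same$r == 1))
  sym <- rf_diversity(list(mu, -mu, mu, -mu), mu)
  expect_equal(median(sym$r), 0)
  expect_true(is.na(sym$p_value) || sym$p_value > 0.9)

  # diverse population: mean above zero, wide spread
  set.seed(5)
  cells <- lapply(1:60, function(i) {
    0.6 * mu + gaussian_map(g8, runif(1, 30, 110), runif(1, 15, 50), 8) -
      gaussian_map(g8, runif(1, 30, 110), runif(1, 15, 50), 8)
  })
  div <- rf_diversity(cells, mu)
  expect_gt(div$mean_r, 0)
  expect_lt(div$p_value, 0.01)
  expect_gte(diff(div$range), 1.0)
})

test_that("knn_neighbors matches an exhaustive sort and breaks ties by id", {
  set.seed(6)
  mono <- data.frame(id = 1:100, class = sample(c("ON", "OFF"), 100, TRUE),
                     x1 = runif(100, 0, 900), x2 = runif(100, 0, 540),
                     x3 = runif(100, 150, 360))
  target <- c(450, 270, 250)
  nb <- knn_neighbors(target, mono, 5)
  for (pol in c("ON", "OFF")) {
    m <- mono[mono$class == pol, ]
    d <- sqrt((m$x1 - target[1])^2 + (m$x2 - target[2])^2 + (m$x3 - target[3])^2)
    expect_equal(nb[[tolower(pol)]]$id, m$id[order(d)][1:5])
  }
  # tie case: four equidistant cells, selection by id
  ring <- data.frame(id = c(9, 3, 7, 1), class = "ON",
                     x1 = c(10, -10, 0, 0), x2 = c(0, 0, 10, -10), x3 = 0)
  ring <- rbind(ring, data.frame(id = 5:6, class = "OFF",
                                 x1 = 0, x2 = 0, x3 = 1))
  nb2 <- knn_neighbors(c(0, 0, 0), ring, 2)
  expect_equal(nb2$on$id, c(1, 3))
  expect_error(knn_neighbors(c(0, 0, 0), ring, 3), "OFF")
})

test_that("nnls_fit recovers exact decompositions and obeys KKT", {
  # orthogonal components with known weights
  phi1 <- matrix(0, 8, 18); phi1[3, 4] <- 1
  phi2 <- matrix(0, 8, 18); phi2[6, 12] <- 1
  fit <- nnls_fit(0.7 * phi1 + 0.3 * phi2, list(phi1, phi2), list())
  expect_equal(fit$weights_on, c(0.7, 0.3), tolerance = 1e-8)
  expect_equal(fit$fit_corr, 1)
  expect_equal(fit$n90[["on"]], 2L)  # 0.7 < 0.9 needs both

  # target orthogonal to every neighbor: all weights zero
  phi3 <- matrix(0, 8, 18); phi3[1, 1] <- 1
  fit0 <- nnls_fit(phi3, list(phi1), list(phi2))
  expect_true(all(c(fit0$weights_on, fit0$weights_off) == 0))

  # dense simplex grid-search oracle on two neighbors
  set.seed(7)
  for (rep in 1:5) {
    a <- gaussian_map(g8, runif(1, 30, 110), runif(1, 15, 50), 9)
    b <- gaussian_map(g8, runif(1, 30, 110), runif(1, 15, 50), 9)
    target <- runif(1, 0, 1) * a - runif(1, 0, 1) * b +
      matrix(rnorm(144, 0, 0.05), 8)
    fit <- nnls_fit(target, list(a), list(b))
    ws <- seq(0, 1.5, 0.01)
    sse <- outer(ws, ws, Vectorize(function(w1, w2)
      sum((as.numeric(target) - w1 * as.numeric(a) + w2 * as.numeric(b))^2)))
    best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    expect_lt(abs(fit$weights_on - ws[best[1]]), 0.011)
    expect_lt(abs(fit$weights_off - ws[best[2]]), 0.011)
    # KKT: gradient non-negative at zero weights
    Phi <- cbind(as.numeric(a), -as.numeric(b))
    w <- c(fit$weights_on, fit$weights_off)
    grad <- -2 * t(Phi) %*% (as.numeric(target) - Phi %*% w)
    expect_true(all(grad[w == 0] >= -1e-8))
  }
})

test_that("weight recovery from planted sparse composites", {
  pop <- quick_population(8, n_on = 120, n_off = 200, n_simple = 40,
                          n_complex = 0)
  mono <- pop$cells[pop$cells$class %in% c("ON", "OFF"), ]
  mono_tab <- data.frame(id = mono$id, class = mono$class,
                         x1 = mono$x1, x2 = mono$x2, x3 = mono$x3)
  mono_maps <- stats::setNames(lapply(mono$id, function(i) {
    m <- pop$maps[[i]]; if (is.null(m$on)) m$off else m$on
  }), mono$id)
  simple <- pop$cells[pop$cells$class == "SIMPLE", ]
  srf_true <- lapply(simple$id, function(i)
    pop$maps[[i]]$on - pop$maps[[i]]$off)

  cosims <- sapply(seq_len(nrow(simple)), function(j) {
    i <- simple$id[j]
    k <- 6
    nb <- knn_neighbors(as.numeric(simple[j, c("x1", "x2", "x3")]),
                        mono_tab, k)
    fit <- nnls_fit(srf_true[[j]],
                    mono_maps[as.character(nb$on$id)],
                    mono_maps[as.character(nb$off$id)],
                    on_ids = nb$on$id, off_ids = nb$off$id)
    w_true <- pop$weights[[i]]
    tru <- c(w_true$on_w[match(nb$on$id, w_true$on_ids)],
             w_true$off_w[match(nb$off$id, w_true$off_ids)])
    tru[is.na(tru)] <- 0
    est <- c(fit$weights_on, fit$weights_off)
    sum(tru * est) / sqrt(sum(tru^2) * sum(est^2))
  })
  expect_gte(median(cosims), 0.99)

  # at kernel SNR ~ 5 (map energy over noise energy), cosine similarity
  # stays high when the neighborhood matches the generative one (k = 3
  # components per polarity)
  set.seed(99)
  snr_sd <- function(m, snr = 5) norm(m, "F") / (snr * sqrt(length(m)))
  noisy_maps <- lapply(mono_maps, function(m)
    m + matrix(rnorm(length(m), 0, snr_sd(m)), nrow(m)))
  cos_noisy <- sapply(seq_len(nrow(simple)), function(j) {
    i <- simple$id[j]
    tgt <- srf_true[[j]] +
      matrix(rnorm(144, 0, snr_sd(srf_true[[j]])), 8)
    nb <- knn_neighbors(as.numeric(simple[j, c("x1", "x2", "x3")]),
                        mono_tab, 3)
    fit <- nnls_fit(tgt, noisy_maps[as.character(nb$on$id)],
                    noisy_maps[as.character(nb$off$id)])
    w_true <- pop$weights[[i]]
    tru <- c(w_true$on_w[match(nb$on$id, w_true$on_ids)],
             w_true$off_w[match(nb$off$id, w_true$off_ids)])
    tru[is.na(tru)] <- 0
    est <- c(fit$weights_on, fit$weights_off)
    if (sum(est^2) == 0 || sum(tru^2) == 0) return(0)
    sum(tru * est) / sqrt(sum(tru^2) * sum(est^2))
  })
  expect_gte(median(cos_noisy), 0.9)
})

test_that("sweep_k saturates at the generative neighborhood size", {
  pop <- quick_population(9, n_on = 120, n_off = 200, n_simple = 30,
                          n_complex = 0)
  mono <- pop$cells[pop$cells$class %in% c("ON", "OFF"), ]
  mono_tab <- data.frame(id = mono$id, class = mono$class,
                         x1 = mono$x1, x2 = mono$x2, x3 = mono$x3)
  mono_maps <- stats::setNames(lapply(mono$id, function(i) {
    m <- pop$maps[[i]]; if (is.null(m$on)) m$off else m$on
  }), mono$id)
  simple <- pop$cells[pop$cells$class == "SIMPLE", ]
  srf <- lapply(simple$id, function(i) pop$maps[[i]]$on - pop$maps[[i]]$off)
  sw <- sweep_k(simple, srf, mono_tab, mono_maps, k_range = c(1:6, 8),
                epsilon = 0.01)
  expect_true(all(diff(sw$summary$median) > -1e-9))  # monotone in k
  expect_lte(sw$k_saturation, 4)  # composites use <= 3 components/polarity
  expect_gte(sw$summary$median[sw$summary$k == 3], 0.99)

  # pure-noise targets stay near the chance level for k regressors
  set.seed(10)
  noise_rfs <- lapply(seq_len(nrow(simple)), function(i)
    matrix(rnorm(144), 8))
  swn <- sweep_k(simple, noise_rfs, mono_tab, mono_maps, k_range = c(2, 5))
  expect_lt(max(swn$summary$median), 0.45)
})

test_that("weight sparsity summaries match hand cases and planted Dirichlet", {
  f1 <- nnls_fit(matrix(c(1, rep(0, 143)), 8),
                 list(matrix(c(1, rep(0, 143)), 8)), list())
  ws <- weight_sparsity(list(f1))
  expect_equal(ws$on$cumulative[1], 1)
  expect_equal(ws$on$n90, 1L)

  # equal weights over 5 neighbors need all 5 for 90%
  maps <- lapply(1:5, function(i) {
    m <- matrix(0, 8, 18); m[1, i] <- 1; m
  })
  target <- Reduce(`+`, maps) / 5
  f2 <- nnls_fit(target, maps, list())
  expect_equal(f2$n90[["on"]], 5L)

  # sparse Dirichlet truth: few components dominate
  pop <- quick_population(12, n_on = 120, n_off = 200, n_simple = 30,
                          n_complex = 0)
  n90s <- sapply(which(pop$cells$class == "SIMPLE"), function(i) {
    w <- sort(pop$weights[[i]]$on_w, decreasing = TRUE)
    which(cumsum(w) / sum(w) >= 0.9)[1]
  })
  expect_lte(mean(n90s), 3)
})

test_that("sparser ON cells sit farther from their targets than OFF cells", {
  mkfits <- function(n_on, n_off, seed) {
    set.seed(seed)
    mono <- data.frame(
      id = seq_len(n_on + n_off),
      class = rep(c("ON", "OFF"), c(n_on, n_off)),
      x1 = runif(n_on + n_off, 0, 900), x2 = runif(n_on + n_off, 0, 540),
      x3 = runif(n_on + n_off, 150, 360))
    lapply(1:60, function(i) {
      target <- c(runif(1, 100, 800), runif(1, 100, 440), runif(1, 150, 360))
      nb <- knn_neighbors(target, mono, 5)
      structure(list(weights_on = rep(1, 5), weights_off = rep(1, 5),
                     distances = list(on = nb$on$distance,
                                      off = nb$off$distance)),
                class = "neighborhood_fit")
    })
  }
  # the 27/55 imbalance regime: ON half as dense as OFF
  p_imb <- sapply(1:20, function(s) {
    res <- neighbor_distance_comparison(mkfits(100, 200, s))
    c(res$p_value < 0.05, res$median_on > res$median_off)
  })
  expect_gte(mean(p_imb[1, ] & p_imb[2, ]), 0.8)
  # equal densities: no systematic direction, and far fewer rejections than
  # the imbalanced case (the pooled distances are within-target dependent,
  # so the rank-sum p is anti-conservative and nominal calibration is not
  # expected from this construction)
  nulls <- sapply(1:20, function(s) {
    res <- neighbor_distance_comparison(mkfits(150, 150, s + 50))
    c(p = res$p_value, dm = res$median_on - res$median_off)
  })
  expect_gte(mean(nulls["p", ] > 0.05), 0.5)
  expect_lt(abs(mean(nulls["dm", ] > 0) - 0.5), 0.35)
  # degenerate: all co-located
  mono0 <- data.frame(id = 1:20, class = rep(c("ON", "OFF"), 10),
                      x1 = 0, x2 = 0, x3 = 0)
  f0 <- lapply(1:10, function(i) {
    nb <- knn_neighbors(c(0, 0, 0), mono0, 2)
    structure(list(weights_on = rep(1, 2), weights_off = rep(1, 2),
                   distances = list(on = nb$on$distance,
                                    off = nb$off$distance)),
              class = "neighborhood_fit")
  })
  res0 <- neighbor_distance_comparison(f0)
  expect_true(is.na(res0$p_value) || res0$p_value > 0.99)
})
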