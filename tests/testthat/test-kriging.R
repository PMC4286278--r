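test_that("exponential-power correlation matches its closed form", {
  expect_equal(exp_power_correlation(0, 0.01, 1), 1)
  # phi solving exp(-phi * 250) = 0.05
  phi <- -log(0.05) / 250
  expect_equal(exp_power_correlation(250, phi, 1), 0.05)
  # kappa = 2: doubling distance quadruples the log correlation
  f1 <- exp_power_correlation(10, 0.001, 2)
  f2 <- exp_power_correlation(20, 0.001, 2)
  expect_equal(log(f2), 4 * log(f1))
  expect_error(exp_power_correlation(-1, 0.01, 1), "nonnegative")
  # bounds and monotonicity on a grid
  d <- seq(0, 300, by = 10)
  for (kappa in c(0.95, 1.5, 2)) {
    f <- exp_power_correlation(d, 0.01, kappa)
    expect_true(all(f >= 0 & f <= 1))       # may underflow at extreme d
    expect_true(all(f[d <= 100] > 0))
    expect_true(all(diff(f) <= 0))
  }
})

test_that("phi prior interval honours both correlation anchors", {
  pri <- kriging_priors()
  expect_gt(pri$kappa_min, 0.9)
  for (kappa in c(pri$kappa_min + 0.01, 1.2, 2)) {
    pb <- phi_bounds(kappa, pri)
    expect_lt(pb[1], pb[2])
    expect_gte(exp_power_correlation(pri$d_min, pb[2], kappa), 0.95 - 1e-12)
    expect_lte(exp_power_correlation(pri$d_max, pb[1], kappa), 0.05 + 1e-12)
  }
})

test_that("noiseless regression limit recovers the slope", {
  set.seed(21)
  m <- 15
  xy <- cbind(runif(m, 0, 50), runif(m, 0, 50))
  D <- as.matrix(dist(xy))
  z_s <- runif(m, 20, 45)
  y <- 1.2 + 0.05 * z_s + rnorm(m, 0, 1e-3)     # sigma2 -> 0 world
  f <- fit_kriging(y, z_s, D, kriging_priors(nugget = 1e-6),
                   quick_kriging(seed = 22))
  expect_lt(abs(mean(f$params$beta) - 0.05), 0.005)
  expect_lt(abs(mean(f$params$alpha) - 1.2), 0.15)
  expect_lt(mean(f$params$sigma2), 0.01)
})

test_that("input validation and duplicate-monitor jitter work", {
  D <- matrix(c(0, 1, 1, 0), 2)
  expect_error(fit_kriging(c(1, 2), c(1, 2), D, kriging_priors(),
                           quick_kriging(seed = 1)), "3 monitors")
  D3 <- matrix(0, 3, 3)
  D3[1, 2] <- D3[2, 1] <- 1; D3[1, 3] <- D3[3, 1] <- 2
  # duplicate location: d(2,3) = 0
  expect_warning(fit_kriging(c(3, 3.1, 3.2), c(30, 31, 32), D3,
                             kriging_priors(),
                             kriging_config(n_chains = 1, n_warmup = 50,
                                            n_samples = 50, thin = 1,
                                            seed = 2)),
                 "jitter")
})

test_that("prediction interpolates exactly at monitors with zero nugget", {
  set.seed(23)
  m <- 8
  xy <- cbind(runif(m, 0, 40), runif(m, 0, 40))
  D <- as.matrix(dist(xy))
  z_s <- runif(m, 20, 40)
  y <- 1.5 + 0.04 * z_s + 0.1 * rnorm(m)
  f <- fit_kriging(y, z_s, D, kriging_priors(nugget = 0),
                   quick_kriging(seed = 24))
  # cells at the monitor locations
  pc <- predict_cells(f, z_s, D, D, n_draws = 50, seed = 25)
  for (d in 1:50)
    expect_equal(log(pc[d, ]), y, tolerance = 1e-4)
})

test_that("far-away cells fall back to the regression mean", {
  set.seed(26)
  m <- 8
  xy <- cbind(runif(m, 0, 30), runif(m, 0, 30))
  D <- as.matrix(dist(xy))
  z_s <- runif(m, 20, 40)
  y <- 1.5 + 0.04 * z_s + 0.05 * rnorm(m)
  f <- fit_kriging(y, z_s, D, kriging_priors(), quick_kriging(seed = 27))
  z_far <- 30
  d_far <- matrix(5000, 1, m)               # >> d_max
  pc <- predict_cells(f, z_far, d_far, matrix(0, 1, 1), n_draws = 400,
                      seed = 28)
  expected <- mean(f$params$alpha + f$params$beta * z_far)
  expect_lt(abs(mean(log(pc)) - expected), 3 * sd(log(pc)) / sqrt(10))
})

test_that("joint predictive draws carry spatial correlation", {
  set.seed(29)
  m <- 8
  xy <- cbind(runif(m, 0, 200), runif(m, 0, 200))
  D <- as.matrix(dist(xy))
  z_s <- rep(30, m)
  y <- 1.5 + 0.04 * z_s + 0.15 * rnorm(m)
  f <- fit_kriging(y, z_s, D, kriging_priors(), quick_kriging(seed = 30))
  # two nearby cells far from monitors vs two mutually distant cells
  cells_xy <- rbind(c(500, 500), c(501, 500), c(900, 0))
  dcm <- sqrt(outer(cells_xy[, 1], xy[, 1], "-")^2 +
              outer(cells_xy[, 2], xy[, 2], "-")^2)
  dcc <- as.matrix(dist(cells_xy))
  pc <- log(predict_cells(f, rep(30, 3), dcm, dcc, n_draws = 600,
                          seed = 31))
  expect_gt(cor(pc[, 1], pc[, 2]), 0.8)     # 1 km apart
  expect_lt(abs(cor(pc[, 1], pc[, 3])), 0.35)
})

test_that("aggregation to municipalities is an exact weighted mean", {
  draws <- rbind(c(30, 50, 10, 20), c(40, 60, 0, 80))
  W <- matrix(0, 4, 2)
  W[1:2, 1] <- 0.5
  W[3:4, 2] <- 0.5
  agg <- aggregate_to_municipality(draws, W)
  expect_equal(agg, rbind(c(40, 15), c(50, 40)))
  # identity when one cell per municipality
  expect_equal(aggregate_to_municipality(draws, diag(4)), draws)
  # linearity
  expect_equal(aggregate_to_municipality(3 * draws, W), 3 * agg)
  # failure modes
  expect_error(aggregate_to_municipality(draws, matrix(0, 4, 1)),
               "no cells")
  Wbad <- W; Wbad[1, 1] <- 0.7
  expect_error(aggregate_to_municipality(draws, Wbad), "sum to 1")
  # equal-weight builder covers every cell exactly once
  reg <- make_lattice_region(3, 4, seed = 1)
  Wr <- municipality_weights(reg)
  expect_equal(colSums(Wr), rep(1, reg$n))
  expect_equal(rowSums(Wr > 0), rep(1, nrow(reg$cells)))
})

test_that("LOOCV is near-perfect on noiseless dense data and unbiased", {
  set.seed(32)
  m <- 12
  xy <- cbind(runif(m, 0, 20), runif(m, 0, 20))
  D <- as.matrix(dist(xy))
  z_s <- runif(m, 20, 40)
  y <- 1.5 + 0.04 * z_s                      # exact linear field, no noise
  cv <- loocv(y, z_s, D, kriging_priors(nugget = 1e-8),
              quick_kriging(seed = 33))
  expect_lt(cv$rmse_log, 0.02)
  expect_lt(abs(cv$fb_percent), 1)
  expect_error(loocv(y[1:3], z_s[1:3], D[1:3, 1:3], kriging_priors(),
                     quick_kriging(seed = 1)), "4 monitors")
})
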