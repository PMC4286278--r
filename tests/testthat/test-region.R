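test_that("lattice geometry and adjacency are correct", {
  reg <- make_lattice_region(2, 1, seed = 1)
  expect_equal(reg$n, 4)
  expect_true(all(lengths(reg$adjacency) == 2))  # all corners on a 2x2

  reg5 <- make_lattice_region(5, 1, seed = 1)
  interior <- 13  # row 3, col 3 in column-major order
  expect_equal(lengths(reg5$adjacency)[interior], 4L)
  # symmetry, no self-neighbours
  for (i in seq_len(reg5$n)) {
    expect_false(i %in% reg5$adjacency[[i]])
    for (j in reg5$adjacency[[i]]) expect_true(i %in% reg5$adjacency[[j]])
  }
  expect_error(make_lattice_region(0), "side")
  expect_error(make_lattice_region(4, cells_per_muni = 3), "perfect square")
})

test_that("fixed seeds reproduce regions, truths and studies bit-exactly", {
  a <- make_lattice_region(10, 1, seed = 1)
  b <- make_lattice_region(10, 1, seed = 1)
  expect_identical(a, b)
  ta <- simulate_truth(a, truth_config(), seed = 3)
  tb <- simulate_truth(b, truth_config(), seed = 3)
  expect_identical(ta, tb)
  sa <- observe_study(ta, a, n_monitors = 10, seed = 4)
  sb <- observe_study(tb, b, n_monitors = 10, seed = 4)
  expect_identical(sa$deaths_5yr, sb$deaths_5yr)
  expect_identical(sa$od_counts, sb$od_counts)
  expect_identical(sa$monitors, sb$monitors)
  expect_false(identical(
    make_lattice_region(10, 1, seed = 1)$pop2001,
    make_lattice_region(10, 1, seed = 2)$pop2001))
})

test_that("every municipality has one province and provinces one capital", {
  reg <- make_lattice_region(7, 4, seed = 2)
  expect_true(all(!is.na(reg$province)))
  for (p in unique(reg$province))
    expect_equal(sum(reg$capital[reg$province == p]), 1)
  expect_true(all(reg$pop2001 >= 1))
  expect_equal(nrow(reg$cells), reg$n * 4)
})

test_that("degenerate generative parameters collapse as stated", {
  reg <- make_lattice_region(4, 1, seed = 1)
  tr <- simulate_truth(reg, truth_config(tau_u2 = 0, tau_v2 = 0), seed = 1)
  expect_equal(tr$rates, rep(exp(truth_config()$baseline_log_rate), reg$n))

  tr2 <- simulate_truth(reg, truth_config(effect_sd = 0), seed = 1)
  expect_equal(var(tr2$effects), 0)

  tr3 <- simulate_truth(reg, truth_config(gravity_lambda_km = 0), seed = 1)
  expect_true(all(tr3$commuting_probs == 0))

  expect_error(simulate_truth(reg, truth_config(tau_u2 = -1), seed = 1),
               "nonnegative")
})

test_that("commuting rows satisfy the probability and count constraints", {
  for (seed in 1:3) {
    reg <- make_lattice_region(5, 1, seed = seed)
    tr <- simulate_truth(reg, truth_config(), seed = seed)
    rs <- rowSums(tr$commuting_probs)
    expect_true(all(rs < 1))
    expect_true(all(diag(tr$commuting_probs) == 0))
    st <- observe_study(tr, reg, n_monitors = 5, seed = seed)
    expect_true(all(rowSums(st$od_counts) <= reg$pop2001))
    expect_true(all(st$od_counts >= 0))
  }
})

test_that("zero commuting probabilities give zero observed counts", {
  reg <- make_lattice_region(3, 1, seed = 1)
  tr <- simulate_truth(reg, truth_config(gravity_lambda_km = 0), seed = 1)
  st <- observe_study(tr, reg, n_monitors = 3, seed = 1)
  expect_true(all(st$od_counts == 0))
})

test_that("noiseless monitors with identity distortion read the field", {
  reg <- make_lattice_region(3, 1, seed = 2)
  tr <- simulate_truth(reg, truth_config(), seed = 2)
  st <- observe_study(tr, reg, n_monitors = 4, monitor_noise_sd = 0,
                      seed = 2, grid_distort = c(0, 1), grid_error_sd = 0)
  expect_equal(st$monitors$value, tr$field_cells[st$monitors$cell])
  expect_equal(st$grid$z, tr$field_cells)
  expect_error(observe_study(tr, reg, n_monitors = 100, seed = 1),
               "exceeds")
})

test_that("observed deaths and flows match their stated moments", {
  # deaths: rate 0.01, pop 10,000, 5 yr -> mean 500, checked over 1,000
  # replicates within 3 MC standard errors
  reg1 <- make_lattice_region(2, 1, seed = 1)
  reg1$pop2001 <- rep(10000, 4)
  tr <- simulate_truth(reg1, truth_config(tau_u2 = 0, tau_v2 = 0,
                                          baseline_log_rate = log(0.01),
                                          gravity_lambda_km = 0), seed = 1)
  deaths <- unlist(lapply(1:250, function(s)
    observe_study(tr, reg1, n_monitors = 2, seed = s)$deaths_5yr))
  expect_equal(length(deaths), 1000)
  se <- sqrt(500 / length(deaths))
  expect_lt(abs(mean(deaths) - 500), 3 * se)

  # flows: Binomial(pop2001, p) means over 500 replicate observations
  reg <- make_lattice_region(3, 1, seed = 3)
  tr2 <- simulate_truth(reg, truth_config(), seed = 3)
  p12 <- tr2$commuting_probs[1, 2]
  cnt <- vapply(1:500, function(s)
    observe_study(tr2, reg, n_monitors = 2, seed = s)$od_counts[1, 2],
    numeric(1))
  m <- reg$pop2001[1] * p12
  se <- sqrt(m * (1 - p12) / 500)
  expect_lt(abs(mean(cnt) - m), 4 * se)
})

test_that("study CSV round trip preserves the data", {
  st <- small_study()
  dir <- tempfile("study")
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir,
    c("municipalities.csv", "adjacency.csv", "od.csv", "monitors.csv",
      "grid.csv", "truth.csv", "city_effects.csv")))))
  back <- read_study(dir)
  expect_equal(back$region$pop2001, st$region$pop2001)
  expect_equal(back$region$adjacency, st$region$adjacency)
  expect_equal(back$deaths_5yr, st$deaths_5yr)
  expect_equal(back$od_counts, unname(st$od_counts))
  expect_equal(back$monitors$value, st$monitors$value)
  expect_equal(back$truth_muni$true_rate, st$truth$rates)
  unlink(dir, recursive = TRUE)
})

test_that("draw matrices round trip through the long CSV format", {
  m <- matrix(rnorm(20), 4, 5)
  path <- tempfile(fileext = ".csv")
  write_draws(m, path, "rate")
  expect_equal(read_draws(path), m)
  unlink(path)
})
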