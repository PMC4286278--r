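# Inputs for engine-level tests are built directly (no MCMC): truth-centred
# lognormal rate/concentration draws and normal effect draws keep these
# tests fast while exercising the full engine.
mc_inputs <- function(study, nd = 200, seed = 81) {
  set.seed(seed)
  n <- study$region$n
  base_r <- matrix(rep(study$truth$rates, each = nd), nd, n)
  base_x <- matrix(rep(study$truth$field_muni, each = nd), nd, n)
  list(rates = base_r * exp(matrix(rnorm(nd * n, 0, 0.05), nd, n)),
       conc = base_x * exp(matrix(rnorm(nd * n, 0, 0.08), nd, n)),
       eff = matrix(rnorm(nd * n, 1e-3, 5e-4), nd, n))
}

test_that("identical master seeds give bit-identical impact draws", {
  st <- small_study()
  inp <- mc_inputs(st)
  post <- posterior_from_counts(st$od_counts, st$region$pop2001)
  cfg <- mc_config(n_draws = 50, seed = 82)
  a <- run_monte_carlo(inp$rates, inp$conc, inp$eff, post,
                       st$region$pop2007, cfg)
  b <- run_monte_carlo(inp$rates, inp$conc, inp$eff, post,
                       st$region$pop2007, cfg)
  expect_identical(a$scenarios, b$scenarios)
  cfg2 <- mc_config(n_draws = 50, seed = 83)
  c <- run_monte_carlo(inp$rates, inp$conc, inp$eff, post,
                       st$region$pop2007, cfg2)
  expect_false(identical(a$scenarios$RS0$A, c$scenarios$RS0$A))
})

test_that("input validation names the failing dimension", {
  st <- small_study()
  inp <- mc_inputs(st, nd = 20)
  post <- posterior_from_counts(st$od_counts, st$region$pop2001)
  expect_error(run_monte_carlo(inp$rates, inp$conc, inp$eff, post,
                               st$region$pop2007,
                               mc_config(n_draws = 100, seed = 1)),
               "fewer than n_draws")
  expect_error(run_monte_carlo(inp$rates, inp$conc[, 1:3], inp$eff, post,
                               st$region$pop2007,
                               mc_config(n_draws = 10, seed = 1)),
               "dimension mismatch")
})

test_that("degenerate identical inputs reproduce the fixture exactly", {
  fx <- fixture3()
  nd <- 20
  rep_rows <- function(v) matrix(v, nd, length(v), byrow = TRUE)
  flows <- array(0L, c(nd, 3, 3))
  for (d in seq_len(nd)) flows[d, , ] <- fx$exit
  cfg <- mc_config(n_draws = nd, seed = 84, scenarios = "RS0",
                   expected_counts = TRUE)
  out <- run_monte_carlo(rep_rows(fx$r), rep_rows(fx$x), rep_rows(fx$beta),
                         NULL, fx$pop, cfg, flows = flows)
  want <- oracle_abc(fx$pop, fx$r, fx$x, fx$beta, fx$exit,
                     scenario_threshold(fx$x, "RS0"))
  for (d in c(1, nd)) {
    expect_equal(out$scenarios$RS0$A[d, ], want$A, tolerance = 1e-12)
    expect_equal(out$scenarios$RS0$B[d, ], want$B, tolerance = 1e-12)
    expect_equal(out$scenarios$RS0$C[d, ], want$C, tolerance = 1e-12)
  }
  expect_equal(out$scenarios$RS0$AD_AB, out$scenarios$RS0$A +
                 out$scenarios$RS0$B)
})

test_that("zero commuting collapses the engine to the static pipeline", {
  st <- small_study()
  nd <- 100
  inp <- mc_inputs(st, nd = nd)
  flows <- array(0L, c(nd, st$region$n, st$region$n))
  cfg <- mc_config(n_draws = nd, seed = 85, scenarios = c("RS0", "RS1"),
                   expected_counts = TRUE)
  out <- run_monte_carlo(inp$rates, inp$conc, inp$eff, NULL,
                         st$region$pop2007, cfg, flows = flows)
  for (s in c("RS0", "RS1")) {
    sc <- out$scenarios[[s]]
    expect_true(all(sc$B == 0) && all(sc$C == 0))
    # direct static evaluation, draw by draw
    for (d in c(1, 50, 100)) {
      y <- st$region$pop2007 * inp$rates[d, ]
      x0 <- scenario_threshold(inp$conc[d, ], s)
      expect_equal(sc$AD_AB[d, ],
                   attributable_static(y, inp$eff[d, ], inp$conc[d, ], x0),
                   tolerance = 1e-12)
    }
    expect_equal(sc$AD_AB, sc$AD_AC)
  }
})

test_that("row-aligned draws preserve between-municipality correlation", {
  # concentrations share one regional shock per draw; permuting each
  # column breaks the correlation and must shrink the spread of the total
  st <- small_study()
  n <- st$region$n
  nd <- 400
  set.seed(86)
  shock <- rnorm(nd, 0, 8)
  conc <- pmax(outer(shock, rep(1, n)) + 35 +
                 matrix(rnorm(nd * n, 0, 1), nd, n), 1)
  rates <- matrix(rep(st$truth$rates, each = nd), nd, n)
  eff <- matrix(1e-3, nd, n)
  flows <- array(0L, c(nd, n, n))
  cfg <- mc_config(n_draws = nd, seed = 87, scenarios = "RS0",
                   expected_counts = TRUE)
  joint <- run_monte_carlo(rates, conc, eff, NULL, st$region$pop2007,
                           cfg, flows = flows)
  perm <- apply(conc, 2, sample)
  broken <- run_monte_carlo(rates, perm, eff, NULL, st$region$pop2007,
                            cfg, flows = flows)
  sd_joint <- sd(rowSums(joint$scenarios$RS0$AD_AB))
  sd_broken <- sd(rowSums(broken$scenarios$RS0$AD_AB))
  expect_gt(sd_joint, 2 * sd_broken)
})

test_that("summaries match the sort-based percentile oracle", {
  set.seed(88)
  # direct oracle equivalence on the documented example
  draws <- 0:9
  expect_equal(commutad:::cri80(draws), c(0.9, 4.5, 8.1))
  for (k in 1:50) {
    x <- rnorm(sample(10:200, 1))
    q <- quantile(x, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
    expect_equal(q, c(oracle_quantile(x, 0.1), oracle_quantile(x, 0.5),
                      oracle_quantile(x, 0.9)))
  }
})

test_that("summarize_impact groups, orders and bounds correctly", {
  st <- small_study()
  inp <- mc_inputs(st, nd = 150)
  post <- posterior_from_counts(st$od_counts, st$region$pop2001)
  cfg <- mc_config(n_draws = 150, seed = 89)
  out <- run_monte_carlo(inp$rates, inp$conc, inp$eff, post,
                         st$region$pop2007, cfg)
  s <- summarize_impact(out, st$region$pop2007, "province", st$region)
  expect_equal(nrow(s), length(unique(st$region$province)) * 4)
  expect_true(all(s$ad_ab_lo80 <= s$ad_ab_median &
                  s$ad_ab_median <= s$ad_ab_hi80))
  expect_true(all(s$pr_ad_positive >= 0 & s$pr_ad_positive <= 1))
  expect_true(all(s$pr_c_gt_b >= 0 & s$pr_c_gt_b <= 1))
  # region median of the total differs from the sum of municipality
  # medians in general, and the group sums are per-draw (sum-then-
  # summarize)
  sm <- summarize_impact(out, st$region$pop2007, "municipality", st$region,
                         scenario = "RS0")
  sr <- summarize_impact(out, st$region$pop2007, "region", st$region,
                         scenario = "RS0")
  expect_equal(sr$ad_ab_median,
               median(rowSums(out$scenarios$RS0$AD_AB)))
  expect_false(isTRUE(all.equal(sr$ad_ab_median, sum(sm$ad_ab_median))))
  # invariance to municipality ordering
  perm <- sample(st$region$n)
  out2 <- out
  for (f in names(out2$scenarios$RS0))
    out2$scenarios$RS0[[f]] <- out2$scenarios$RS0[[f]][, perm]
  reg2 <- st$region
  reg2$province <- reg2$province[perm]
  reg2$capital <- reg2$capital[perm]
  s2 <- summarize_impact(out2, st$region$pop2007[perm], "province", reg2,
                         scenario = "RS0")
  s1 <- summarize_impact(out, st$region$pop2007, "province", st$region,
                         scenario = "RS0")
  expect_equal(s1$ad_ab_median, s2$ad_ab_median)
  expect_equal(s1$acr_median, s2$acr_median)
})

test_that("report tables have the contracted structure", {
  st <- small_study()
  inp <- mc_inputs(st, nd = 120)
  post <- posterior_from_counts(st$od_counts, st$region$pop2001)
  out <- run_monte_carlo(inp$rates, inp$conc, inp$eff, post,
                         st$region$pop2007,
                         mc_config(n_draws = 120, seed = 90))
  dir <- tempfile("report")
  tabs <- report_tables(out, st$region, out_dir = dir)
  np <- length(unique(st$region$province))
  t1_rs0 <- tabs$table1[tabs$table1$scenario == "RS0", ]
  expect_equal(nrow(t1_rs0), np + 1)
  expect_true("Total" %in% t1_rs0$province)
  # Total row is the per-draw regional sum summarized, not a column sum
  expect_equal(t1_rs0$ad_ab_median[t1_rs0$province == "Total"],
               median(rowSums(out$scenarios$RS0$AD_AB)))
  expect_true(all(tabs$table3$pr_c_gt_b >= 0 & tabs$table3$pr_c_gt_b <= 1))
  expect_equal(nrow(tabs$log_ratio), st$region$n)
  expect_true(all(tabs$log_ratio$flag %in%
                    c("finite", "exporter_only", "importer_only",
                      "undefined")))
  expect_true(all(file.exists(file.path(dir, c("table1.csv", "table2.csv",
                                               "table3.csv",
                                               "log_ratio.csv")))))
  unlink(dir, recursive = TRUE)
})

test_that("the command-line interface round trips a small study", {
  skip_if_not_installed("optparse")
  d1 <- tempfile("cli_study"); d2 <- tempfile("cli_out")
  cli_main(c("simulate", "--side", "4", "--cells-per-muni", "1",
             "--n-monitors", "6", "--seed", "3", "--out-dir", d1))
  expect_true(file.exists(file.path(d1, "municipalities.csv")))
  suppressWarnings(
    cli_main(c("impact", "--in-dir", d1, "--scenarios", "RS0,RS1",
               "--draws", "60", "--seed", "4", "--out-dir", d2)))
  expect_true(file.exists(file.path(d2, "impact_RS0.csv")))
  expect_true(file.exists(file.path(d2, "runlog.json")))
  expect_true(file.exists(file.path(d2, "table1.csv")))
  log <- jsonlite::fromJSON(file.path(d2, "runlog.json"))
  expect_equal(log$draws, 60)
  unlink(c(d1, d2), recursive = TRUE)
})
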