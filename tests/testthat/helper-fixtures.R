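# Shared fixtures and independent oracles.  Oracles are deliberately
# written as plain scalar loops, independent of the package's vectorized
# code paths.

quick_bym <- function(seed) {
  bym_config(n_chains = 2, n_warmup = 500, n_samples = 500, thin = 2,
             seed = seed)
}

quick_kriging <- function(seed) {
  kriging_config(n_chains = 2, n_warmup = 600, n_samples = 600, thin = 2,
                 seed = seed)
}

quick_meta <- function(seed) {
  meta_config(n_chains = 2, n_warmup = 500, n_samples = 500, thin = 2,
              seed = seed)
}

# the printed 3-municipality fixture
fixture3 <- function() {
  exit <- matrix(0, 3, 3)
  exit[1, 2] <- 3000; exit[2, 1] <- 1000; exit[3, 1] <- 2000
  list(pop = c(30000, 20000, 10000),
       r = c(0.01, 0.01, 0.02),
       x = c(50, 30, 15),
       beta = c(0.001, 0.0005, 0.002),
       exit = exit)
}

# independent scalar evaluation of the A/B/C decomposition in
# expected-counts mode (threshold x0 given per municipality)
oracle_abc <- function(pop, r, x, beta, exit, x0, share = 1 / 3) {
  n <- length(pop)
  ad1 <- function(y, b, xx, x0x) {
    if (xx > x0x && b > 0) y - y / exp(b * (xx - x0x)) else 0
  }
  A <- B <- C <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(n)) if (j != i) tot <- tot + exit[i, j]
    A[i] <- ad1((pop[i] - share * tot) * r[i], beta[i], x[i], x0[i])
    for (j in seq_len(n)) {
      if (j == i) next
      B[i] <- B[i] + ad1(share * exit[i, j] * r[i], beta[j], x[j], x0[j])
      C[i] <- C[i] + ad1(share * exit[j, i] * r[j], beta[i], x[i], x0[i])
    }
  }
  list(A = A, B = B, C = C)
}

# sort-based percentile oracle: linear interpolation between order
# statistics at p in [0, 1]
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# small study used by several unit tests (cached per session)
.fixture_env <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(side = 5, cells_per_muni = 1,
                                         n_monitors = 8, seed = 11)
  .fixture_env$study
}
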