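# BYM disease mapping: Poisson likelihood, exchangeable + ICAR random
# effects, MCMC smoothing of small-area mortality rates.

#' ICAR full-conditional moments of one spatial effect
#'
#' For the intrinsic CAR prior, the conditional distribution of `v[i]` given
#' its neighbours is normal with mean the neighbour average and variance
#' `tau_v2 / n_i`.  An isolated node (no neighbours) follows the fixed-zero
#' contract: mean 0, infinite variance, and the sampler pins `v[i] = 0`.
#'
#' @param v numeric vector of spatial effects.
#' @param i municipality index.
#' @param adjacency list of integer neighbour vectors.
#' @param tau_v2 conditional variance parameter (> 0).
#' @return named numeric `c(mean, variance)`; variance is `Inf` for an
#'   isolated node.
#' @examples
#' icar_conditional(c(0, 1, 2, 3), 1, list(2:4, c(1L,3L), c(1L,2L), 1L), 0.3)
#' @export
icar_conditional <- function(v, i, adjacency, tau_v2) {
  stopifnot(tau_v2 > 0, i >= 1, i <= length(adjacency))
  nb <- adjacency[[i]]
  if (length(nb) == 0) return(c(mean = 0, variance = Inf))
  c(mean = mean(v[nb]), variance = tau_v2 / length(nb))
}

#' Configuration for the BYM fit
#'
#' The variance priors are the conventional weakly-informative inverse-gamma
#' choice of the disease-mapping literature, InvGamma(0.5, 0.0005) on both
#' the exchangeable and the ICAR variance; the intercept gets a vague normal
#' prior.  Defaults run 4 chains of 2,000 warmup + 2,000 sampling
#' iterations, thinned by 8 so the pipeline consumes 1,000 total draws.
#'
#' @param prior_shape,prior_rate inverse-gamma hyperparameters shared by
#'   `tau_u2` and `tau_v2` (both > 0).
#' @param intercept_prior_sd sd of the normal prior on the intercept.
#' @param n_chains,n_warmup,n_samples,thin MCMC run lengths; the total draw
#'   count is `n_chains * n_samples / thin`.
#' @param seed integer seed (mandatory).
#' @return list of class `bym_config`.
#' @export
bym_config <- function(prior_shape = 0.5, prior_rate = 0.0005,
                       intercept_prior_sd = 10,
                       n_chains = 4, n_warmup = 2000, n_samples = 2000,
                       thin = 8, seed) {
  if (missing(seed)) stop("`seed` is mandatory in bym_config()")
  stopifnot(prior_shape > 0, prior_rate > 0, intercept_prior_sd > 0,
            n_chains >= 1, n_warmup >= 0, n_samples >= thin, thin >= 1,
            n_samples %% thin == 0)
  structure(as.list(environment()), class = "bym_config")
}

# adjacency list -> 0-based CSR (idx, ptr)
adjacency_csr <- function(adjacency) {
  deg <- lengths(adjacency)
  list(idx = as.integer(unlist(adjacency, use.names = FALSE) - 1L),
       ptr = as.integer(c(0L, cumsum(deg))))
}

# rank of the ICAR precision: (#non-isolated nodes) - (#connected components)
icar_rank <- function(adjacency) {
  n <- length(adjacency)
  deg <- lengths(adjacency)
  seen <- deg == 0
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      i <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      new <- adjacency[[i]][!seen[adjacency[[i]]]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
  }
  as.integer(sum(deg > 0) - comps)
}

# split-chain potential-scale-reduction statistic for one scalar;
# x: iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  x <- cbind(x[seq_len(half), , drop = FALSE],
             x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(x); n <- nrow(x)
  mu <- colMeans(x)
  B <- n * var(mu)
  W <- mean(apply(x, 2, var))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the BYM smoothing model by MCMC
#'
#' Samples the posterior of `{alpha, u, v, tau_u2, tau_v2}` under
#' `deaths_i ~ Poisson(person_years_i * r_i)` with
#' `r_i = exp(alpha + u_i + v_i)`, `u_i` exchangeable normal and `v` ICAR
#' with a sum-to-zero constraint.  Shrinks crude small-area rates toward
#' both the local (neighbourhood) and the general mean.  Isolated
#' municipalities have `v_i` fixed at 0 and their heterogeneity carried by
#' `u_i`.  Split-chain convergence statistics are computed for every rate,
#' the intercept and both variances; a warning names municipalities whose
#' rate statistic exceeds 1.05.
#'
#' @param deaths nonnegative integer deaths per municipality (e.g. 5-year
#'   totals).
#' @param person_years positive person-years at risk per municipality (five
#'   times the census population for 5-year death counts).
#' @param adjacency list of integer neighbour vectors (symmetric, no self).
#' @param config a [bym_config()].
#' @return Object of class `rate_samples`: list with `draws` (n_draws x
#'   n_munis matrix of rates, deaths per person-year), `alpha`, `u`, `v`,
#'   `tau_u2`, `tau_v2` draw vectors/matrices, `diagnostics` (data.frame
#'   `param`, `rhat`) and `config`.
#' @export
fit_bym <- function(deaths, person_years, adjacency, config) {
  stopifnot(inherits(config, "bym_config"))
  n <- length(deaths)
  stopifnot(length(person_years) == n, length(adjacency) == n,
            all(deaths >= 0), all(person_years > 0))
  for (i in seq_len(n)) {
    for (j in adjacency[[i]]) {
      if (j == i) stop("self-neighbour at municipality ", i)
      if (!(i %in% adjacency[[j]]))
        stop("adjacency not symmetric at pair (", i, ", ", j, ")")
    }
  }
  csr <- adjacency_csr(adjacency)
  rank_v <- icar_rank(adjacency)
  keep_per_chain <- config$n_samples %/% config$thin
  seeds <- spawn_seeds(config$seed, config$n_chains)

  chains <- vector("list", config$n_chains)
  alpha0 <- log((sum(deaths) + 0.5) / sum(person_years))
  for (ch in seq_len(config$n_chains)) {
    set.seed(seeds[ch])
    chains[[ch]] <- bym_chain_cpp(
      as.numeric(deaths), as.numeric(person_years),
      csr$idx, csr$ptr,
      config$n_warmup, config$n_samples, config$thin,
      config$prior_shape, config$prior_rate,
      config$prior_shape, config$prior_rate,
      config$intercept_prior_sd, rank_v,
      alpha0 + rnorm(1, 0, 0.2),
      rnorm(n, 0, 0.05), numeric(n),
      exp(rnorm(1, log(0.01), 0.5)), exp(rnorm(1, log(0.01), 0.5)))
  }

  bindc <- function(field) do.call(rbind, lapply(chains, `[[`, field))
  alpha <- unlist(lapply(chains, `[[`, "alpha"))
  u <- bindc("u"); v <- bindc("v")
  tau_u2 <- unlist(lapply(chains, `[[`, "tau_u2"))
  tau_v2 <- unlist(lapply(chains, `[[`, "tau_v2"))
  draws <- exp(alpha + u + v)

  per_chain <- function(vec) matrix(vec, nrow = keep_per_chain,
                                    ncol = config$n_chains)
  rhats <- c(vapply(seq_len(n), function(i)
               split_rhat(matrix(log(draws[, i]), nrow = keep_per_chain)),
               numeric(1)),
             split_rhat(per_chain(alpha)),
             split_rhat(per_chain(log(tau_u2))),
             split_rhat(per_chain(log(tau_v2))))
  diagnostics <- data.frame(
    param = c(paste0("rate[", seq_len(n), "]"), "alpha", "tau_u2", "tau_v2"),
    rhat = rhats)
  bad <- which(rhats[seq_len(n)] > 1.05)
  if (length(bad) && config$n_chains >= 2)
    warning("BYM convergence statistic > 1.05 for rate(s): ",
            paste(bad, collapse = ", "))

  structure(list(draws = draws, alpha = alpha, u = u, v = v,
                 tau_u2 = tau_u2, tau_v2 = tau_v2,
                 diagnostics = diagnostics, config = config),
            class = "rate_samples")
}

#' @export
print.rate_samples <- function(x, ...) {
  cat(sprintf("rate_samples: %d draws x %d municipalities; max rhat %.3f\n",
              nrow(x$draws), ncol(x$draws), max(x$diagnostics$rhat,
                                                na.rm = TRUE)))
  invisible(x)
}

#' Smoothed-versus-crude rate comparison table
#'
#' Per municipality: crude rate `deaths / person_years`, posterior mean,
#' median and 80% credible interval of the smoothed rate, and the shrinkage
#' factor `(crude - posterior mean) / crude` (0 when crude is 0).
#'
#' @param samples a `rate_samples` from [fit_bym()].
#' @param deaths,person_years the data the model was fitted to.
#' @return data.frame with one row per municipality.
#' @export
smoothed_vs_crude_report <- function(samples, deaths, person_years) {
  stopifnot(inherits(samples, "rate_samples"))
  n <- ncol(samples$draws)
  stopifnot(length(deaths) == n, length(person_years) == n)
  crude <- deaths / person_years
  pm <- colMeans(samples$draws)
  qs <- apply(samples$draws, 2, quantile, probs = c(0.1, 0.5, 0.9),
              type = 7, names = FALSE)
  data.frame(municipality = seq_len(n), crude = crude,
             posterior_mean = pm, posterior_median = qs[2, ],
             lower80 = qs[1, ], upper80 = qs[3, ],
             shrinkage = ifelse(crude > 0, (crude - pm) / crude, 0))
}
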