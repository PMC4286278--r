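# Normal-normal Bayesian random-effects meta-analysis of city-specific
# PM10 effects, with posterior-predictive draws of a generic-city effect
# for municipalities without their own time-series estimate.

#' Priors for the effect meta-analysis
#'
#' Effects are on the log-relative-risk-per-1-ug/m3 scale, so a normal
#' prior sd of 1 on the pooled mean is extremely vague (typical effects are
#' ~1e-3).  The heterogeneity sd gets a half-normal prior.  Setting
#' `tau_fixed = 0` collapses the model to the fixed-effect (common-effect)
#' limit, handled in closed conjugate form.
#'
#' @param mu_sd prior sd of the pooled mean effect.
#' @param tau_scale half-normal scale of the heterogeneity sd.
#' @param tau_fixed optional fixed value for the heterogeneity sd (0 gives
#'   the fixed-effect limit); `NULL` to estimate it.
#' @return list of class `meta_priors`.
#' @export
meta_priors <- function(mu_sd = 1, tau_scale = 0.005, tau_fixed = NULL) {
  stopifnot(mu_sd > 0, tau_scale > 0)
  if (!is.null(tau_fixed)) stopifnot(tau_fixed >= 0)
  structure(as.list(environment()), class = "meta_priors")
}

#' MCMC configuration for the meta-analysis
#'
#' @inheritParams bym_config
#' @return list of class `meta_config`.
#' @export
meta_config <- function(n_chains = 4, n_warmup = 1000, n_samples = 1000,
                        thin = 4, seed) {
  if (missing(seed)) stop("`seed` is mandatory in meta_config()")
  stopifnot(n_chains >= 1, n_samples %% thin == 0)
  structure(as.list(environment()), class = "meta_config")
}

#' Fit the random-effects meta-analysis
#'
#' Model: `estimate_k ~ N(theta_k, se_k^2)`, `theta_k ~ N(mu, tau^2)`, with
#' a vague normal prior on `mu` and a half-normal prior on `tau`.  Gibbs
#' updates for `theta` and `mu`; adaptive random-walk Metropolis on
#' `log tau`.  With `tau_fixed = 0` the posterior of `mu` is conjugate
#' normal (precision-weighted mean of the estimates plus the prior) and is
#' sampled exactly, with all `theta_k = mu`.
#'
#' @param estimates data.frame with columns `city_id`, `estimate` (log RR
#'   per ug/m3) and `se` (> 0); at least 2 cities.
#' @param priors a [meta_priors()].
#' @param config a [meta_config()].
#' @return Object of class `meta_fit`: list with `mu`, `tau` (draw
#'   vectors), `theta` (draws x cities matrix), `city_id`, `diagnostics`,
#'   `priors`, `config`.
#' @export
fit_meta <- function(estimates, priors = meta_priors(), config) {
  stopifnot(inherits(priors, "meta_priors"), inherits(config, "meta_config"))
  stopifnot(all(c("city_id", "estimate", "se") %in% names(estimates)))
  K <- nrow(estimates)
  if (K < 2) stop("at least 2 cities are required (heterogeneity unidentified)")
  if (any(estimates$se <= 0)) stop("standard errors must be positive")
  est <- estimates$estimate
  se2 <- estimates$se^2
  n_total <- config$n_chains * (config$n_samples %/% config$thin)

  if (!is.null(priors$tau_fixed) && priors$tau_fixed == 0) {
    # fixed-effect limit: exact conjugate posterior for the common effect
    prec <- sum(1 / se2) + 1 / priors$mu_sd^2
    mean_mu <- sum(est / se2) / prec
    set.seed(config$seed)
    mu <- rnorm(n_total, mean_mu, sqrt(1 / prec))
    theta <- matrix(mu, n_total, K)
    colnames(theta) <- estimates$city_id
    return(structure(list(mu = mu, tau = rep(0, n_total), theta = theta,
                          city_id = estimates$city_id,
                          posterior_mean_mu = mean_mu,
                          diagnostics = data.frame(param = "mu", rhat = 1),
                          priors = priors, config = config),
                     class = "meta_fit"))
  }

  keep_per_chain <- config$n_samples %/% config$thin
  seeds <- spawn_seeds(config$seed, config$n_chains)
  run_chain <- function(seed) {
    set.seed(seed)
    mu <- mean(est) + rnorm(1, 0, sd(est))
    fixed_tau <- !is.null(priors$tau_fixed)
    tau <- if (fixed_tau) priors$tau_fixed else abs(rnorm(1, 0, priors$tau_scale))
    tau <- max(tau, 1e-8)
    theta <- est
    scl <- 0.5; acc <- 0L; tries <- 0L
    out <- matrix(NA_real_, keep_per_chain, 2 + K)
    kept <- 0L
    for (it in seq_len(config$n_warmup + config$n_samples)) {
      prec_k <- 1 / se2 + 1 / tau^2
      theta <- rnorm(K, (est / se2 + mu / tau^2) / prec_k, sqrt(1 / prec_k))
      prec_mu <- K / tau^2 + 1 / priors$mu_sd^2
      mu <- rnorm(1, sum(theta) / tau^2 / prec_mu, sqrt(1 / prec_mu))
      if (!fixed_tau) {
        # RW on log tau; half-normal prior with log-scale Jacobian
        lp <- function(lt) {
          t2 <- exp(2 * lt)
          -K * lt - sum((theta - mu)^2) / (2 * t2) -
            t2 / (2 * priors$tau_scale^2) + lt
        }
        prop <- log(tau) + rnorm(1, 0, scl)
        tries <- tries + 1L
        if (log(runif(1)) < lp(prop) - lp(log(tau))) {
          tau <- exp(prop); acc <- acc + 1L
        }
        if (it <= config$n_warmup && it %% 50 == 0) {
          r <- acc / tries
          if (r > 0.5) scl <- scl * 1.2 else if (r < 0.3) scl <- scl / 1.2
          acc <- 0L; tries <- 0L
        }
      }
      if (it > config$n_warmup &&
          (it - config$n_warmup) %% config$thin == 0) {
        kept <- kept + 1L
        out[kept, ] <- c(mu, tau, theta)
      }
    }
    out
  }
  chains <- lapply(seeds, run_chain)
  draws <- do.call(rbind, chains)
  mu <- draws[, 1]; tau <- draws[, 2]
  theta <- draws[, -(1:2), drop = FALSE]
  colnames(theta) <- estimates$city_id
  rhats <- c(split_rhat(matrix(mu, nrow = keep_per_chain)),
             split_rhat(matrix(log(tau), nrow = keep_per_chain)))
  structure(list(mu = mu, tau = tau, theta = theta,
                 city_id = estimates$city_id,
                 posterior_mean_mu = mean(mu),
                 diagnostics = data.frame(param = c("mu", "tau"),
                                          rhat = rhats),
                 priors = priors, config = config),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("meta_fit: %d draws, %d cities; mu = %.5f, tau = %.5f (posterior means)\n",
              length(x$mu), ncol(x$theta), mean(x$mu), mean(x$tau)))
  invisible(x)
}

#' Posterior-predictive generic-city effects
#'
#' Per posterior draw `d`, samples `beta_new ~ N(mu_d, tau_d^2)` -- the
#' effect a new, unobserved city would have.  Its variance is the posterior
#' variance of `mu` plus the expected heterogeneity, so the predictive is
#' always at least as wide as the pooled-mean posterior.
#'
#' @param fit a `meta_fit`.
#' @param n_new number of generic columns to draw.
#' @param seed integer seed.
#' @param shared if `TRUE` (default) one generic effect per draw is shared
#'   by all `n_new` columns (a single "generic city"); if `FALSE` each
#'   column gets an independent predictive draw.
#' @return n_draws x n_new matrix of log RR per ug/m3.
#' @export
predictive_effect <- function(fit, n_new = 1, seed = 1L, shared = TRUE) {
  stopifnot(inherits(fit, "meta_fit"), n_new >= 1)
  set.seed(seed)
  nd <- length(fit$mu)
  if (shared) {
    matrix(rnorm(nd, fit$mu, fit$tau), nd, n_new)
  } else {
    matrix(rnorm(nd * n_new, fit$mu, fit$tau), nd, n_new)
  }
}

#' Assemble the draw-aligned effect matrix for a region
#'
#' Municipalities mapped to a "known" city take that city's posterior
#' `theta` draws; all others take the generic posterior-predictive draws.
#'
#' @param region a `region_graph` (or any list with element `n`).
#' @param known_city_map named integer/character vector: names are
#'   municipality indices, values are `city_id`s present in the fit.
#' @param fit a `meta_fit`.
#' @param generic matrix from [predictive_effect()] with either 1 column
#'   (shared) or one column per unmapped municipality.
#' @return n_draws x n_munis matrix of log RR per ug/m3.
#' @export
assign_effects <- function(region, known_city_map, fit, generic) {
  stopifnot(inherits(fit, "meta_fit"))
  n <- region$n
  nd <- length(fit$mu)
  stopifnot(nrow(generic) == nd)
  out <- matrix(NA_real_, nd, n)
  mapped <- integer(0)
  if (length(known_city_map)) {
    idx <- as.integer(names(known_city_map))
    stopifnot(all(idx >= 1), all(idx <= n))
    pos <- match(as.character(known_city_map), as.character(fit$city_id))
    if (anyNA(pos))
      stop("unmapped estimate id(s): ",
           paste(known_city_map[is.na(pos)], collapse = ", "))
    out[, idx] <- fit$theta[, pos, drop = FALSE]
    mapped <- idx
  }
  other <- setdiff(seq_len(n), mapped)
  if (length(other)) {
    if (ncol(generic) == 1) {
      out[, other] <- generic[, rep(1, length(other))]
    } else {
      stopifnot(ncol(generic) >= length(other))
      out[, other] <- generic[, seq_along(other)]
    }
  }
  out
}

#' Convert between log RR per ug/m3 and percent change per 10 ug/m3
#'
#' `percent = 100 * (exp(10 * beta) - 1)`; e.g. `beta = log(1.01)/10`
#' corresponds to +1% mortality per 10 ug/m3.
#'
#' @param beta log relative risk per 1 ug/m3.
#' @return percent variation per 10 ug/m3.
#' @export
log_rr_to_percent10 <- function(beta) 100 * (exp(10 * beta) - 1)

#' @rdname log_rr_to_percent10
#' @param percent percent variation per 10 ug/m3.
#' @return log relative risk per 1 ug/m3.
#' @export
percent10_to_log_rr <- function(percent) log(1 + percent / 100) / 10
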