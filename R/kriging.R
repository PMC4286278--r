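# Bayesian universal kriging of the annual PM10 surface: log monitor
# concentrations are multivariate normal with mean linear in the
# deterministic-model predictions and an exponential-power spatial
# covariance; MCMC over (alpha, beta, sigma2, phi, kappa) and joint
# conditional-Gaussian prediction at the grid cells.

#' Exponential-power spatial correlation
#'
#' `exp(-phi * d^kappa)`: `kappa = 1` is the exponential model, `kappa = 2`
#' the Gaussian; `phi` controls the decay rate with distance.
#'
#' @param d distance (km), >= 0 (vector or matrix).
#' @param phi decay rate (> 0), in km^-kappa.
#' @param kappa smoothness exponent in (0, 2].
#' @return correlation(s) in (0, 1].
#' @examples
#' exp_power_correlation(250, -log(0.05) / 250, 1)  # 0.05
#' @export
exp_power_correlation <- function(d, phi, kappa) {
  if (any(d < 0)) stop("distances must be nonnegative")
  stopifnot(phi > 0, kappa > 0, kappa <= 2)
  exp(-phi * d^kappa)
}

#' Priors for the kriging model
#'
#' Vague normal priors on the regression coefficients, half-normal on the
#' spatial sd, and a joint uniform prior on `(kappa, phi)` operationalizing
#' "correlation ~ 1 at the minimum distance and ~ 0 at the maximum
#' distance": given `kappa`, `phi` is uniform on the interval where the
#' correlation is at least `corr_hi` at `d_min` km and at most `corr_lo` at
#' `d_max` km.  That interval is nonempty only for
#' `kappa >= log(log(corr_lo)/log(corr_hi)) / log(d_max/d_min)` (~0.92 at
#' the defaults), which becomes the lower prior bound of `kappa`.  A small
#' nugget keeps the covariance well conditioned.
#'
#' @param coef_sd prior sd of alpha and beta.
#' @param sigma_scale half-normal scale of the spatial sd (log scale).
#' @param d_min,d_max anchor distances in km (defaults 3, 250).
#' @param corr_hi,corr_lo correlations required at `d_min` / `d_max`
#'   (defaults 0.95, 0.05, reading "one"/"zero" as nondegenerate bounds).
#' @param nugget additive log-scale nugget variance (default 1e-4).
#' @return list of class `kriging_priors`.
#' @export
kriging_priors <- function(coef_sd = 10, sigma_scale = 1,
                           d_min = 3, d_max = 250,
                           corr_hi = 0.95, corr_lo = 0.05, nugget = 1e-4) {
  stopifnot(d_min > 0, d_min < d_max, corr_lo < corr_hi,
            corr_lo > 0, corr_hi < 1, nugget >= 0)
  kappa_min <- log(log(corr_lo) / log(corr_hi)) / log(d_max / d_min)
  if (kappa_min >= 2)
    stop("correlation constraints admit no kappa in (0, 2]")
  structure(c(as.list(environment())), class = "kriging_priors")
}

#' @rdname kriging_priors
#' @param kappa smoothness value at which to evaluate the `phi` bounds.
#' @param priors a `kriging_priors`.
#' @return `phi_bounds()`: `c(lo, hi)` of the uniform conditional prior.
#' @export
phi_bounds <- function(kappa, priors) {
  c(lo = -log(priors$corr_lo) / priors$d_max^kappa,
    hi = -log(priors$corr_hi) / priors$d_min^kappa)
}

#' MCMC configuration for the kriging fit
#'
#' @param n_chains,n_warmup,n_samples,thin run lengths; total draws are
#'   `n_chains * n_samples / thin`.
#' @param seed integer seed (mandatory).
#' @return list of class `kriging_config`.
#' @export
kriging_config <- function(n_chains = 2, n_warmup = 1000, n_samples = 1000,
                           thin = 2, seed) {
  if (missing(seed)) stop("`seed` is mandatory in kriging_config()")
  stopifnot(n_chains >= 1, n_samples %% thin == 0)
  structure(as.list(environment()), class = "kriging_config")
}

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

# log MVN density of resid with covariance S (chol-based); -Inf on failure
mvn_loglik <- function(resid, S) {
  L <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  w <- backsolve(L, resid, transpose = TRUE)
  -sum(log(diag(L))) - 0.5 * sum(w * w) - 0.5 * length(resid) * log(2 * pi)
}

#' Fit the Bayesian universal kriging model
#'
#' `log(x) ~ MVN(alpha + beta * z_s, sigma2 * f(d; kappa, phi) + nugget I)`
#' with `f` the exponential-power correlation.  Coefficients are updated by
#' conjugate Gibbs draws; `(kappa, phi, sigma2)` by an adaptive joint
#' random-walk Metropolis step on transformed coordinates respecting the
#' prior support.
#'
#' @param monitor_log log annual average concentrations at the monitors.
#' @param z_s deterministic-model predictions (ug/m3) at the monitor cells.
#' @param distances symmetric monitor-to-monitor distance matrix (km).
#' @param priors a [kriging_priors()].
#' @param config a [kriging_config()].
#' @return Object of class `kriging_fit`: list with `params` (data.frame of
#'   draws: `alpha`, `beta`, `sigma2`, `phi`, `kappa`), `diagnostics`,
#'   `data` (inputs, for prediction), `priors`, `config`.
#' @export
fit_kriging <- function(monitor_log, z_s, distances,
                        priors = kriging_priors(), config) {
  stopifnot(inherits(priors, "kriging_priors"),
            inherits(config, "kriging_config"))
  m <- length(monitor_log)
  if (m < 3) stop("at least 3 monitors are required")
  stopifnot(length(z_s) == m, all(dim(distances) == c(m, m)))
  if (max(abs(distances - t(distances))) > 1e-8 || any(diag(distances) != 0))
    stop("`distances` must be symmetric with a zero diagonal")
  off <- distances[upper.tri(distances)]
  if (any(off <= 0)) {
    warning("duplicate monitor locations: jittering zero distances")
    distances[distances <= 0] <- 1e-3
    diag(distances) <- 0
  }

  X <- cbind(1, z_s)
  keep_per_chain <- config$n_samples %/% config$thin
  seeds <- spawn_seeds(config$seed, config$n_chains)
  km <- priors$kappa_min

  run_chain <- function(seed) {
    set.seed(seed)
    fit0 <- stats::lm.fit(X, monitor_log)
    ab <- fit0$coefficients + rnorm(2, 0, 0.05)
    s2 <- max(var(fit0$residuals), 4 * priors$nugget) * exp(rnorm(1, 0, 0.3))
    t1 <- rnorm(1, 0, 0.5)            # kappa
    t2 <- rnorm(1, 0, 0.5)            # phi fraction within its box
    t3 <- log(s2)                     # log sigma2
    scl <- 0.3
    acc <- 0L; tries <- 0L

    unpack <- function(t1, t2, t3) {
      kappa <- km + (2 - km) * invlogit(t1)
      pb <- phi_bounds(kappa, priors)
      phi <- pb[1] + invlogit(t2) * (pb[2] - pb[1])
      list(kappa = kappa, phi = phi, sigma2 = exp(t3))
    }
    # log posterior kernel in (t1,t2,t3) given coefficients
    lpost <- function(t1, t2, t3, ab) {
      p <- unpack(t1, t2, t3)
      S <- p$sigma2 * exp_power_correlation(distances, p$phi, p$kappa)
      diag(S) <- diag(S) + priors$nugget
      sig <- sqrt(p$sigma2)
      mvn_loglik(monitor_log - X %*% ab, S) -
        sig^2 / (2 * priors$sigma_scale^2) + log(sig) +   # half-normal + Jac
        log(invlogit(t1)) + log(1 - invlogit(t1)) +        # uniform kappa Jac
        log(invlogit(t2)) + log(1 - invlogit(t2))          # uniform phi Jac
    }

    out <- matrix(NA_real_, keep_per_chain, 5)
    lp <- lpost(t1, t2, t3, ab)
    kept <- 0L
    n_iter <- config$n_warmup + config$n_samples
    for (it in seq_len(n_iter)) {
      # Gibbs for (alpha, beta)
      p <- unpack(t1, t2, t3)
      S <- p$sigma2 * exp_power_correlation(distances, p$phi, p$kappa)
      diag(S) <- diag(S) + priors$nugget
      Si <- chol2inv(chol(S))
      V <- crossprod(X, Si %*% X) + diag(1 / priors$coef_sd^2, 2)
      Vc <- chol2inv(chol(V))
      mu <- Vc %*% crossprod(X, Si %*% monitor_log)
      ab <- drop(mu + t(chol(Vc)) %*% rnorm(2))
      lp <- lpost(t1, t2, t3, ab)

      # joint RW for (kappa, phi, sigma2)
      pr <- c(t1, t2, t3) + rnorm(3, 0, scl)
      lp_new <- lpost(pr[1], pr[2], pr[3], ab)
      tries <- tries + 1L
      if (log(runif(1)) < lp_new - lp) {
        t1 <- pr[1]; t2 <- pr[2]; t3 <- pr[3]
        lp <- lp_new
        acc <- acc + 1L
      }
      if (it <= config$n_warmup && it %% 50 == 0) {
        r <- acc / tries
        if (r > 0.35) scl <- scl * 1.2 else if (r < 0.15) scl <- scl / 1.2
        acc <- 0L; tries <- 0L
      }
      if (it > config$n_warmup &&
          (it - config$n_warmup) %% config$thin == 0) {
        kept <- kept + 1L
        p <- unpack(t1, t2, t3)
        out[kept, ] <- c(ab[1], ab[2], p$sigma2, p$phi, p$kappa)
      }
    }
    out
  }

  chains <- lapply(seeds, run_chain)
  params <- as.data.frame(do.call(rbind, chains))
  names(params) <- c("alpha", "beta", "sigma2", "phi", "kappa")
  rhats <- vapply(seq_len(5), function(j)
    split_rhat(matrix(params[[j]], nrow = keep_per_chain)), numeric(1))
  diagnostics <- data.frame(param = names(params), rhat = rhats)

  structure(list(params = params, diagnostics = diagnostics,
                 data = list(monitor_log = monitor_log, z_s = z_s,
                             distances = distances),
                 priors = priors, config = config),
            class = "kriging_fit")
}

#' @export
print.kriging_fit <- function(x, ...) {
  cat(sprintf("kriging_fit: %d draws; posterior means alpha=%.3f beta=%.4f sigma2=%.4f\n",
              nrow(x$params), mean(x$params$alpha), mean(x$params$beta),
              mean(x$params$sigma2)))
  invisible(x)
}

#' Joint posterior-predictive PM10 draws at grid cells
#'
#' For each parameter draw, simulates the log concentration at every cell
#' from the conditional (kriging) Gaussian given the monitor residuals --
#' jointly across cells, so between-cell correlation is preserved -- and
#' exponentiates to ug/m3.  With a zero nugget the predictive collapses to
#' the observed value at a cell coincident with a monitor (exact
#' interpolation); the default small nugget leaves a correspondingly small
#' residual variance there.
#'
#' @param fit a `kriging_fit`.
#' @param z deterministic-model predictions at all cells.
#' @param dist_cm cells x monitors distance matrix (km).
#' @param dist_cc cells x cells distance matrix (km).
#' @param n_draws number of predictive draws (default: all parameter draws,
#'   recycling from the start if more are requested than available).
#' @param seed integer seed.
#' @return n_draws x n_cells matrix of concentrations (ug/m3).
#' @export
predict_cells <- function(fit, z, dist_cm, dist_cc,
                          n_draws = nrow(fit$params), seed = 1L) {
  stopifnot(inherits(fit, "kriging_fit"))
  nc <- length(z)
  if (anyNA(z)) stop("every cell must have a deterministic prediction z")
  stopifnot(nrow(dist_cm) == nc, ncol(dist_cm) == length(fit$data$z_s),
            all(dim(dist_cc) == c(nc, nc)))
  set.seed(seed)
  np <- nrow(fit$params)
  # evenly spaced across all chains (never a single-chain prefix)
  idx <- if (n_draws <= np) round(seq(1, np, length.out = n_draws)) else
    rep_len(seq_len(np), n_draws)
  y <- fit$data$monitor_log
  zs <- fit$data$z_s
  Dmm <- fit$data$distances
  nug <- fit$priors$nugget
  out <- matrix(NA_real_, n_draws, nc)
  for (d in seq_len(n_draws)) {
    p <- fit$params[idx[d], ]
    Smm <- p$sigma2 * exp_power_correlation(Dmm, p$phi, p$kappa)
    diag(Smm) <- diag(Smm) + nug
    Scm <- p$sigma2 * exp_power_correlation(dist_cm, p$phi, p$kappa)
    Scc <- p$sigma2 * exp_power_correlation(dist_cc, p$phi, p$kappa)
    diag(Scc) <- diag(Scc) + nug
    Li <- chol2inv(chol(Smm))
    W <- Scm %*% Li
    mu <- p$alpha + p$beta * z + drop(W %*% (y - p$alpha - p$beta * zs))
    Cv <- Scc - W %*% t(Scm)
    Cv <- (Cv + t(Cv)) / 2
    diag(Cv) <- diag(Cv) + 1e-12 + 1e-9 * p$sigma2
    out[d, ] <- exp(mu + drop(crossprod(chol(Cv), rnorm(nc))))
  }
  out
}

#' Cell-to-municipality weights
#'
#' Equal (area) weights over the cells each municipality owns, or
#' population-proportional weights are left to the caller via the generic
#' weight-matrix interface of [aggregate_to_municipality()].
#'
#' @param region a `region_graph`.
#' @return n_cells x n_munis matrix whose columns are nonnegative and sum
#'   to 1.
#' @export
municipality_weights <- function(region) {
  stopifnot(inherits(region, "region_graph"))
  W <- matrix(0, nrow(region$cells), region$n)
  for (i in seq_len(region$n)) {
    own <- which(region$cells$muni == i)
    W[own, i] <- 1 / length(own)
  }
  W
}

#' Aggregate cell draws to municipalities
#'
#' Weighted mean on the concentration scale, per draw ("integrating over
#' the predicted cell values").  Aggregation is linear in the cell values.
#'
#' @param cell_draws n_draws x n_cells matrix.
#' @param weights n_cells x n_munis matrix; each column nonnegative, sums
#'   to 1; a zero column (municipality owning no cells) is an error.
#' @return n_draws x n_munis matrix.
#' @export
aggregate_to_municipality <- function(cell_draws, weights) {
  stopifnot(ncol(cell_draws) == nrow(weights))
  if (any(weights < 0)) stop("weights must be nonnegative")
  cs <- colSums(weights)
  if (any(cs == 0)) stop("municipality with no cells: ",
                         paste(which(cs == 0), collapse = ", "))
  if (max(abs(cs - 1)) > 1e-8) stop("weight columns must sum to 1")
  cell_draws %*% weights
}

#' Leave-one-out cross-validation of the kriging model
#'
#' By default fits once on all monitors and computes, for every parameter
#' draw, the exact leave-one-out conditional Gaussian prediction of each
#' monitor from the others (via the precision-matrix identity); with
#' `refit = TRUE` the model is refitted without each monitor.  Predictions
#' are posterior means on the log scale.
#'
#' @param monitor_log,z_s,distances as in [fit_kriging()].
#' @param priors a [kriging_priors()].
#' @param config a [kriging_config()].
#' @param refit refit the model for each fold (slow, exact) instead of
#'   reusing full-data parameter draws.
#' @return list with `rmse_log` (root mean squared error of the log
#'   predictions), `fb_percent` (fractional bias on the log scale, in %),
#'   and `predictions` (posterior-mean log prediction per monitor).
#' @export
loocv <- function(monitor_log, z_s, distances, priors = kriging_priors(),
                  config, refit = FALSE) {
  m <- length(monitor_log)
  if (m < 4) stop("at least 4 monitors are required for LOOCV")
  if (!refit) {
    fit <- fit_kriging(monitor_log, z_s, distances, priors, config)
    P <- fit$params
    pred_acc <- numeric(m)
    for (d in seq_len(nrow(P))) {
      p <- P[d, ]
      S <- p$sigma2 * exp_power_correlation(distances, p$phi, p$kappa)
      diag(S) <- diag(S) + priors$nugget
      Ki <- chol2inv(chol(S))
      r <- monitor_log - p$alpha - p$beta * z_s
      pred_acc <- pred_acc + (monitor_log - (Ki %*% r) / diag(Ki))
    }
    pred <- pred_acc / nrow(P)
  } else {
    pred <- numeric(m)
    seeds <- spawn_seeds(config$seed, m)
    for (i in seq_len(m)) {
      cfg <- config; cfg$seed <- seeds[i]
      f <- fit_kriging(monitor_log[-i], z_s[-i],
                       distances[-i, -i, drop = FALSE], priors, cfg)
      dcm <- matrix(distances[i, -i], nrow = 1)
      P <- f$params
      acc <- 0
      for (d in seq_len(nrow(P))) {
        p <- P[d, ]
        S <- p$sigma2 * exp_power_correlation(f$data$distances, p$phi,
                                              p$kappa)
        diag(S) <- diag(S) + priors$nugget
        k <- p$sigma2 * exp_power_correlation(dcm, p$phi, p$kappa)
        r <- f$data$monitor_log - p$alpha - p$beta * f$data$z_s
        acc <- acc + p$alpha + p$beta * z_s[i] +
          drop(k %*% chol2inv(chol(S)) %*% r)
      }
      pred[i] <- acc / nrow(P)
    }
  }
  mp <- mean(pred); mo <- mean(monitor_log)
  list(rmse_log = sqrt(mean((pred - monitor_log)^2)),
       fb_percent = 200 * (mp - mo) / (mp + mo),
       predictions = pred)
}
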