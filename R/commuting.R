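# Conjugate beta posteriors for intermunicipality commuting probabilities
# and binomial sampling of commuter flows.

#' Conjugate beta posterior of the commuting probabilities
#'
#' With a vague (uniform) beta prior and a binomial likelihood for the
#' census origin-destination count `c_ij` out of `pop_i^2001` trials, the
#' posterior of the commuting probability `p_ij` is
#' `Beta(1 + c_ij, 1 + pop_i^2001 - c_ij)` for every ordered pair `i != j`.
#' The diagonal is ignored (no intramunicipality commuting).
#'
#' @param od_counts n x n integer matrix of commuter counts `c_ij`.
#' @param pop_2001 census population per origin municipality.
#' @return Object of class `commuting_posterior`: list with `a`, `b`
#'   (n x n beta parameters, `NA` diagonal) and `pop_2001`.
#' @examples
#' p <- posterior_from_counts(matrix(c(0, 250, 0, 0), 2, 2, byrow = TRUE),
#'                            c(10000, 5000))
#' c(p$a[1, 2], p$b[1, 2])  # Beta(251, 9751)
#' @export
posterior_from_counts <- function(od_counts, pop_2001) {
  n <- length(pop_2001)
  stopifnot(all(dim(od_counts) == c(n, n)), all(pop_2001 >= 1))
  cmat <- od_counts
  diag(cmat) <- 0
  if (any(cmat < 0)) stop("negative commuting counts")
  if (any(cmat > pop_2001))
    stop("commuting count exceeds origin population for pair(s): ",
         paste(utils::head(which(cmat > pop_2001)), collapse = ", "))
  a <- 1 + cmat
  b <- 1 + pop_2001 - cmat         # pop_2001 recycles down columns = by origin
  diag(a) <- NA_real_
  diag(b) <- NA_real_
  structure(list(a = a, b = b, pop_2001 = as.numeric(pop_2001)),
            class = "commuting_posterior")
}

#' Sample commuter-flow tensors
#'
#' Per Monte Carlo draw, samples every `p_ij ~ Beta(a_ij, b_ij)`
#' independently, then `exit(i,j) ~ Binomial(pop_i^2007, p_ij)`.  The
#' binomial trials use the 2007 intercensual population while the beta
#' posterior comes from 2001 census counts; both populations are kept as
#' distinct fields.  Rows whose sampled flows reach or exceed the origin
#' population are resampled (never expected at realistic probabilities);
#' the number of resampling events is reported.
#'
#' @param posterior a `commuting_posterior`.
#' @param pop_2007 population per municipality used as binomial trials.
#' @param n_draws number of draws (>= 1).
#' @param seed integer seed.
#' @return Object of class `flow_draws`: list with `flows`
#'   (n_draws x n x n integer array, zero diagonal) and `n_resampled`.
#' @export
sample_flows <- function(posterior, pop_2007, n_draws, seed = 1L) {
  stopifnot(inherits(posterior, "commuting_posterior"), n_draws >= 1)
  n <- length(posterior$pop_2001)
  stopifnot(length(pop_2007) == n)
  set.seed(seed)
  flows <- array(0L, c(n_draws, n, n))
  n_resampled <- 0L
  a <- posterior$a
  b <- posterior$b
  off <- which(!is.na(a))          # all ordered pairs i != j, column-major
  orig <- ((off - 1L) %% n) + 1L   # row index = origin
  for (d in seq_len(n_draws)) {
    p <- rbeta(length(off), a[off], b[off])
    cnt <- rbinom(length(off), pop_2007[orig], p)
    M <- matrix(0L, n, n)
    M[off] <- cnt
    bad <- which(rowSums(M) >= pop_2007)
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      n_resampled <- n_resampled + length(bad)
      for (i in bad) {
        sel <- which(orig == i)
        p <- rbeta(length(sel), a[off[sel]], b[off[sel]])
        M[off[sel]] <- rbinom(length(sel), pop_2007[i], p)
      }
      bad <- which(rowSums(M) >= pop_2007)
      guard <- guard + 1L
    }
    if (length(bad))
      stop("could not sample flows below population for municipality ",
           paste(bad, collapse = ", "))
    flows[d, , ] <- M
  }
  structure(list(flows = flows, n_resampled = n_resampled),
            class = "flow_draws")
}

#' Kolmogorov-Smirnov check of sampled commuting probabilities
#'
#' Distance between the empirical distribution of sampled `p_ij` values and
#' the analytic `Beta(a, b)` law -- a verification utility for the sampling
#' machinery.
#'
#' @param samples numeric vector of sampled probabilities (>= 100).
#' @param a,b beta parameters.
#' @return list with `statistic` (KS distance) and `p_value`.
#' @export
ks_check_beta <- function(samples, a, b) {
  if (length(samples) < 100) stop("at least 100 samples are required")
  kt <- suppressWarnings(ks.test(samples, stats::pbeta, a, b))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
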