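# Per-draw attributable-death calculus: counterfactual thresholds,
# the static log-linear AD formula, commuting-split person-time, and the
# A/B/C decomposition with its conservation identity.

#' Reduction-scenario specification
#'
#' Maps an observed annual concentration `x` to its counterfactual
#' threshold `x0`:
#' * `RS0`: `x0 = 20` ug/m3 (WHO annual air-quality guideline);
#' * `RS1`: `x0 = 40` ug/m3 (EU annual limit);
#' * `RS2`: 20% reduction where `x > 20`, or less if sufficient to reach
#'   20 (`x0 = max(0.8 x, 20)`); inactive (no attributable deaths) at or
#'   below 20;
#' * `RS3`: likewise with the 40 ug/m3 limit.
#'
#' A custom scenario is a list with elements `name` and `rule`
#' (a vectorized function of `x` returning `x0 <= x` wherever active).
#'
#' @param name one of `"RS0"`, `"RS1"`, `"RS2"`, `"RS3"`.
#' @return list of class `scenario_spec` with `name` and `rule`.
#' @export
scenario_spec <- function(name) {
  rules <- list(
    RS0 = function(x) rep(20, length(x)),
    RS1 = function(x) rep(40, length(x)),
    RS2 = function(x) ifelse(x > 20, pmax(0.8 * x, 20), x),
    RS3 = function(x) ifelse(x > 40, pmax(0.8 * x, 40), x))
  if (!name %in% names(rules)) stop("unknown scenario: ", name)
  structure(list(name = name, rule = rules[[name]]), class = "scenario_spec")
}

as_scenario <- function(scenario) {
  if (inherits(scenario, "scenario_spec")) return(scenario)
  if (is.character(scenario)) return(scenario_spec(scenario))
  if (is.list(scenario) && is.function(scenario$rule))
    return(structure(scenario, class = "scenario_spec"))
  stop("`scenario` must be a name or a scenario_spec")
}

#' Counterfactual threshold under a scenario
#'
#' @param x annual average concentration(s), ug/m3 (>= 0).
#' @param scenario scenario name or [scenario_spec()].
#' @return threshold(s) `x0` in ug/m3.
#' @examples
#' scenario_threshold(c(35, 50, 22), "RS2")  # 28, 40, 20
#' @export
scenario_threshold <- function(x, scenario) {
  if (any(x < 0)) stop("concentrations must be nonnegative")
  as_scenario(scenario)$rule(x)
}

#' Attributable deaths from the static log-linear relation
#'
#' `AD = y - y / exp(beta+ * (x - x0) * I(x > x0))`, with `beta+` the
#' effect truncated at zero: a negative sampled effect contributes zero
#' attributable deaths (impact is conditional on a harmful exposure).
#' Vectorized over municipalities.
#'
#' @param y deaths (>= 0; may be non-integer expected counts).
#' @param beta log relative risk per ug/m3.
#' @param x annual average concentration, ug/m3.
#' @param x0 counterfactual threshold, ug/m3.
#' @return attributable deaths in `[0, y)`.
#' @export
attributable_static <- function(y, beta, x, x0) {
  if (any(y < 0)) stop("deaths must be nonnegative")
  bp <- pmax(beta, 0)
  y * (1 - exp(-bp * (x - x0) * (x > x0)))
}

#' Expected person-time split between residence and commuting destinations
#'
#' Residents spend a fraction `share` (default one-third: balance between
#' travel time and weekend breaks) of their time in the municipality where
#' they commute.  Expected deaths among the static portion are
#' `mu_S = (pop - share * sum(exit)) * rate`; among commuters to `j`,
#' `mu_C_j = share * exit_j * rate`.  Exactly conserves
#' `mu_S + sum(mu_C) = pop * rate`.
#'
#' @param pop_2007 residence population (person-years at risk).
#' @param flows_out vector of out-commuter counts `exit(i, .)`.
#' @param rate residence mortality rate (per person-year).
#' @param share fraction of commuter time spent at the destination,
#'   in (0, 1).
#' @return list with `mu_S` (scalar) and `mu_C` (vector).
#' @export
expected_person_time <- function(pop_2007, flows_out, rate, share = 1 / 3) {
  stopifnot(share > 0, share < 1, all(flows_out >= 0), rate >= 0)
  if (share * sum(flows_out) >= pop_2007)
    stop("commuter person-time exhausts the population (degenerate)")
  list(mu_S = (pop_2007 - share * sum(flows_out)) * rate,
       mu_C = share * flows_out * rate)
}

#' One draw of the A/B/C attributable-death decomposition
#'
#' For a single Monte Carlo iteration: `A_i` are deaths among residents of
#' `i` attributable to exposure in `i` (static portion); `B_i` deaths among
#' residents of `i` attributable to exposure where they commute;
#' `C_i` deaths among non-residents attributable to exposure in `i`.  The
#' effect is that of the municipality of exposure, the mortality rate that
#' of the municipality of residence.  Death counts `y_i^S` and `y_ij^C` are
#' Poisson draws around the expected person-time (or the expectations
#' themselves in `expected_counts` mode), sampled once and reused in both
#' the B and C sums, which makes `sum(B) == sum(C)` an exact identity.
#'
#' @param rates,conc,effects numeric vectors (one draw, length n).
#' @param exit n x n flow matrix (zero diagonal).
#' @param pop_2007 populations (person-years at risk).
#' @param scenario scenario name or [scenario_spec()].
#' @param share commuter time fraction.
#' @param truncation `"term"` (default): each term uses `max(beta, 0)`;
#'   `"draw"`: the whole draw is zeroed when any sampled effect is
#'   negative.
#' @param expected_counts replace Poisson draws by their means
#'   (deterministic; for testing and oracles).
#' @param y_s,y_c optionally supply pre-sampled death counts (vector /
#'   n x n matrix), e.g. to share them across scenarios within a draw.
#' @return list with `A`, `B`, `C` (vectors), `y_s`, `y_c`.
#' @export
compute_ABC <- function(rates, conc, effects, exit, pop_2007, scenario,
                        share = 1 / 3, truncation = c("term", "draw"),
                        expected_counts = FALSE, y_s = NULL, y_c = NULL) {
  truncation <- match.arg(truncation)
  n <- length(rates)
  stopifnot(length(conc) == n, length(effects) == n,
            length(pop_2007) == n, all(dim(exit) == c(n, n)))
  if (any(diag(exit) != 0)) stop("flow matrix must have a zero diagonal")
  out_tot <- rowSums(exit)
  if (any(share * out_tot >= pop_2007))
    stop("commuter person-time exhausts the population (degenerate)")

  mu_s <- (pop_2007 - share * out_tot) * rates
  mu_c <- share * exit * rates            # row i scaled by rates[i]
  if (is.null(y_s))
    y_s <- if (expected_counts) mu_s else rpois(n, mu_s)
  if (is.null(y_c)) {
    y_c <- if (expected_counts) mu_c else
      matrix(rpois(n * n, mu_c), n, n)
  }
  stopifnot(length(y_s) == n, all(dim(y_c) == c(n, n)))

  if (truncation == "draw" && any(effects < 0)) {
    z <- numeric(n)
    return(list(A = z, B = z, C = z, y_s = y_s, y_c = y_c))
  }
  x0 <- scenario_threshold(conc, scenario)
  frac <- 1 - exp(-pmax(effects, 0) * (conc - x0) * (conc > x0))
  A <- y_s * frac
  Tmat <- y_c * rep(frac, each = n)       # term (i,j) uses (beta_j, x_j)
  list(A = A, B = rowSums(Tmat), C = colSums(Tmat), y_s = y_s, y_c = y_c)
}

#' Attributable community rate
#'
#' Attributable deaths per 100,000 inhabitants: `1e5 * ad / pop`.
#'
#' @param ad attributable deaths.
#' @param pop population (> 0).
#' @return rate per 100,000.
#' @examples
#' round(acr(865.3, 9545441), 1)  # 9.1
#' @export
acr <- function(ad, pop) {
  if (any(pop <= 0)) stop("population must be positive")
  1e5 * ad / pop
}

#' Log ratio of exported to imported attributable deaths
#'
#' `log(C_median / B_median)` per municipality.  Positive values mark net
#' exporters of impact, negative values net importers.  Boundary flags
#' rather than errors: `+Inf` (exporter only, `B = 0 < C`), `-Inf`
#' (importer only), `NaN` (both zero, undefined).
#'
#' @param c_median posterior median of exported deaths `C_i` (>= 0).
#' @param b_median posterior median of imported deaths `B_i` (>= 0).
#' @return numeric vector of log ratios with the flags above.
#' @export
export_import_log_ratio <- function(c_median, b_median) {
  stopifnot(all(c_median >= 0), all(b_median >= 0))
  ifelse(c_median == 0 & b_median == 0, NaN,
         ifelse(b_median == 0, Inf,
                ifelse(c_median == 0, -Inf, log(c_median / b_median))))
}
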