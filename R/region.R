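#' @useDynLib commutad, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois rbinom rbeta rgamma quantile median
#'   ks.test dist sd var
#' @importFrom utils read.csv write.csv
"_PACKAGE"

#' Build a square-lattice study region
#'
#' Constructs a synthetic region of `side^2` municipalities arranged on a
#' square lattice with rook adjacency, standing in for a real administrative
#' map.  Each municipality owns a square block of `cells_per_muni` 4x4 km
#' model-grid cells; provinces are contiguous blocks of the lattice and the
#' highest-population member of each province is flagged as its capital.
#' Populations are log-uniform between `10^pop_log10_range[1]` and
#' `10^pop_log10_range[2]`, capitals are inflated by `capital_pop_factor`
#' (cities are larger), and the 2007 population is the 2001 census value
#' times a uniform intercensual drift.
#'
#' @param side lattice side length (>= 2); the region has `side^2`
#'   municipalities.
#' @param cells_per_muni grid cells owned by each municipality; must be a
#'   perfect square so cells tile a square block (default 4, i.e. 8x8 km
#'   municipalities).
#' @param seed integer seed; fixing it fixes every emitted array.
#' @param pop_log10_range range of log10 population (default 1,000--100,000).
#' @param capital_pop_factor multiplier applied to capital populations.
#' @return An object of class `region_graph`: a list with elements `n`,
#'   `pop2001`, `pop2007`, `adjacency` (list of integer neighbour vectors),
#'   `centroids` (n x 2 matrix, km), `province` (integer label),
#'   `capital` (logical), `cells` (data.frame: `cell`, `muni`, `x`, `y`),
#'   `side`, `cells_per_muni`.
#' @examples
#' reg <- make_lattice_region(3, cells_per_muni = 1, seed = 1)
#' lengths(reg$adjacency)  # corners 2, edges 3, centre 4
#' @export
make_lattice_region <- function(side, cells_per_muni = 4, seed = 1L,
                                pop_log10_range = c(3, 5),
                                capital_pop_factor = 4) {
  if (!is.numeric(side) || length(side) != 1 || side < 2 || side != round(side))
    stop("`side` must be a single integer >= 2")
  csq <- sqrt(cells_per_muni)
  if (cells_per_muni < 1 || csq != round(csq))
    stop("`cells_per_muni` must be a perfect square (1, 4, 9, ...)")
  set.seed(seed)
  side <- as.integer(side)
  csq <- as.integer(csq)
  n <- side * side
  cell_km <- 4                      # 4x4 km model grid
  muni_km <- cell_km * csq

  # municipality (row, col) with column-major index i = (col-1)*side + row
  row <- rep(seq_len(side), times = side)
  col <- rep(seq_len(side), each = side)
  centroids <- cbind(x = (col - 0.5) * muni_km, y = (row - 0.5) * muni_km)

  adjacency <- vector("list", n)
  for (i in seq_len(n)) {
    r <- row[i]; cc <- col[i]
    nb <- integer(0)
    if (r > 1)    nb <- c(nb, i - 1L)
    if (r < side) nb <- c(nb, i + 1L)
    if (cc > 1)    nb <- c(nb, i - side)
    if (cc < side) nb <- c(nb, i + side)
    adjacency[[i]] <- sort(nb)
  }

  # provinces: contiguous blocks from near-equal row/column bands (~3 wide)
  nb_bands <- max(1L, as.integer(ceiling(side / 3)))
  band <- function(idx) {
    if (nb_bands == 1L) return(rep(1L, length(idx)))
    as.integer(cut(idx, breaks = nb_bands, labels = FALSE))
  }
  province <- (band(col) - 1L) * nb_bands + band(row)
  province <- as.integer(factor(province))  # compact labels 1..P

  pop2001 <- round(10^runif(n, pop_log10_range[1], pop_log10_range[2]))
  capital <- logical(n)
  for (p in unique(province)) {
    members <- which(province == p)
    cap <- members[which.max(pop2001[members])]
    capital[cap] <- TRUE
    pop2001[cap] <- round(pop2001[cap] * capital_pop_factor)
  }
  pop2001 <- pmax(pop2001, 1)
  pop2007 <- pmax(round(pop2001 * runif(n, 0.95, 1.10)), 1)

  # grid cells: csq x csq block per municipality
  offs <- (seq_len(csq) - 0.5) * cell_km
  cx <- cy <- muni <- numeric(0)
  for (i in seq_len(n)) {
    ox <- (col[i] - 1) * muni_km
    oy <- (row[i] - 1) * muni_km
    g <- expand.grid(x = ox + offs, y = oy + offs)
    cx <- c(cx, g$x); cy <- c(cy, g$y)
    muni <- c(muni, rep(i, cells_per_muni))
  }
  cells <- data.frame(cell = seq_along(cx), muni = as.integer(muni),
                      x = cx, y = cy)

  structure(list(n = n, pop2001 = as.numeric(pop2001),
                 pop2007 = as.numeric(pop2007), adjacency = adjacency,
                 centroids = centroids, province = province,
                 capital = capital, cells = cells, side = side,
                 cells_per_muni = as.integer(cells_per_muni),
                 cell_km = cell_km),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("region_graph: %d municipalities (%dx%d lattice), %d provinces, %d grid cells\n",
              x$n, x$side, x$side, length(unique(x$province)), nrow(x$cells)))
  invisible(x)
}

#' Generative parameters for the synthetic ground truth
#'
#' Defaults describe a plausible northern-Italian study region: a baseline
#' all-cause mortality rate of 9.5 per 1,000 person-years; modest
#' unstructured (`tau_u2`) and spatially structured (`tau_v2`) log-rate
#' variability; an annual PM10 field around 24--45 ug/m3, elevated near
#' provincial capitals and smoothly varying elsewhere; a mean
#' concentration-response effect of +1% mortality per 10 ug/m3
#' (log RR `log(1.01)/10` per ug/m3) with between-city heterogeneity large
#' enough that some cities have an appreciable probability of a negative
#' sampled effect; and gravity commuting in which roughly 30% of residents
#' (7% in capitals) commute out, preferentially to large and nearby
#' municipalities and to capitals.
#'
#' @param baseline_log_rate log of the regional mortality rate (per
#'   person-year).
#' @param tau_u2,tau_v2 variances of the unstructured and ICAR spatial
#'   log-rate components (must be >= 0).
#' @param field_log_base log of the rural background PM10 (ug/m3).
#' @param field_capital_amp log-scale amplitude of the capital pollution bump.
#' @param field_capital_range_km decay range (km) of the capital bump.
#' @param field_gp_sd,field_gp_range_km sd and exponential-correlation range
#'   of the smooth log-field Gaussian process.
#' @param effect_mean,effect_sd mean and sd of true city effects, log RR per
#'   ug/m3.
#' @param gravity_gamma destination-population exponent of the gravity rule.
#' @param gravity_lambda_km distance-decay scale (km); 0 disables commuting.
#' @param capital_boost multiplicative attraction of capital destinations.
#' @param out_frac,out_frac_capital target out-commuting fraction for
#'   non-capital / capital municipalities.
#' @param p_max hard cap on the total out-commuting probability (< 1).
#' @return list of class `truth_config`.
#' @export
truth_config <- function(baseline_log_rate = log(0.0095),
                         tau_u2 = 0.005, tau_v2 = 0.01,
                         field_log_base = log(24),
                         field_capital_amp = 0.5,
                         field_capital_range_km = 15,
                         field_gp_sd = 0.15, field_gp_range_km = 30,
                         effect_mean = log(1.01) / 10,
                         effect_sd = 6e-4,
                         gravity_gamma = 0.8, gravity_lambda_km = 15,
                         capital_boost = 3,
                         out_frac = 0.30, out_frac_capital = 0.07,
                         p_max = 0.5) {
  if (tau_u2 < 0 || tau_v2 < 0) stop("variance parameters must be nonnegative")
  if (effect_sd < 0) stop("effect_sd must be nonnegative")
  if (p_max <= 0 || p_max >= 1) stop("p_max must lie in (0, 1)")
  structure(as.list(environment()), class = "truth_config")
}

# Simulate a zero-mean GP with exponential correlation exp(-d/range) at the
# given coordinates; range 0 or sd 0 degenerates to iid / zero.
simulate_gp <- function(coords, sd, range_km) {
  m <- nrow(coords)
  if (sd == 0) return(numeric(m))
  if (range_km <= 0) return(rnorm(m, 0, sd))
  D <- as.matrix(dist(coords))
  S <- sd^2 * exp(-D / range_km)
  L <- chol(S + diag(1e-10 * sd^2, m))
  unname(drop(crossprod(L, rnorm(m))))
}

# Draw an ICAR vector on the sum-to-zero subspace: covariance tau_v2 * Q^+,
# Q the graph Laplacian (the proper realization of the improper ICAR prior).
simulate_icar <- function(adjacency, tau_v2) {
  n <- length(adjacency)
  if (tau_v2 == 0) return(numeric(n))
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Q[i, adjacency[[i]]] <- -1
    Q[i, i] <- length(adjacency[[i]])
  }
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  V <- e$vectors[, pos, drop = FALSE]
  lam <- e$values[pos]
  drop(V %*% (rnorm(length(lam)) * sqrt(tau_v2 / lam)))
}

#' Simulate the ground truth of a synthetic region
#'
#' Draws, from the stated generative model, the true mortality rates
#' (log-linear with iid and ICAR spatial components, the generative
#' counterpart of the BYM smoothing model), a smooth annual PM10 field over
#' the grid cells (log-scale capital bumps plus a Gaussian process), true
#' city effects from a normal hierarchy, and gravity-rule commuting
#' probabilities concentrated on capitals.
#'
#' @param region a `region_graph`.
#' @param config a [truth_config()].
#' @param seed integer seed.
#' @return Object of class `ground_truth`: list with `rates` (deaths per
#'   person-year), `field_cells` and `field_muni` (ug/m3), `effects`
#'   (log RR per ug/m3), `commuting_probs` (n x n, zero diagonal, rows
#'   summing to < 1), and the `config` used.
#' @export
simulate_truth <- function(region, config = truth_config(), seed = 1L) {
  stopifnot(inherits(region, "region_graph"))
  if (!inherits(config, "truth_config")) config <- do.call(truth_config, config)
  set.seed(seed)
  n <- region$n

  u <- rnorm(n, 0, sqrt(config$tau_u2))
  v <- simulate_icar(region$adjacency, config$tau_v2)
  rates <- exp(config$baseline_log_rate + u + v)

  # PM10 field on cells: background + nearest-capital bump + smooth GP,
  # log scale; max (not sum) over capitals so a dense capital layout does
  # not pile bumps into implausible concentrations
  cells <- region$cells
  caps <- which(region$capital)
  bump <- numeric(nrow(cells))
  for (k in caps) {
    d <- sqrt((cells$x - region$centroids[k, 1])^2 +
              (cells$y - region$centroids[k, 2])^2)
    bump <- pmax(bump, config$field_capital_amp *
                   exp(-d / config$field_capital_range_km))
  }
  gp <- simulate_gp(cbind(cells$x, cells$y), config$field_gp_sd,
                    config$field_gp_range_km)
  field_cells <- exp(config$field_log_base + bump + gp)
  field_muni <- as.numeric(tapply(field_cells, cells$muni, mean))

  effects <- rnorm(n, config$effect_mean, config$effect_sd)

  # gravity commuting: p_ij ~ pop_j^gamma * exp(-d_ij/lambda), capital boost,
  # rows rescaled to the target out-fraction and capped at p_max
  P <- matrix(0, n, n)
  if (config$gravity_lambda_km > 0) {
    D <- as.matrix(dist(region$centroids))
    W <- outer(rep(1, n), region$pop2001^config$gravity_gamma) *
      exp(-D / config$gravity_lambda_km)
    W <- W * outer(rep(1, n), ifelse(region$capital, config$capital_boost, 1))
    diag(W) <- 0
    target <- ifelse(region$capital, config$out_frac_capital, config$out_frac)
    target <- pmin(target, config$p_max)
    rs <- rowSums(W)
    ok <- rs > 0
    P[ok, ] <- W[ok, , drop = FALSE] * (target[ok] / rs[ok])
  }
  structure(list(rates = rates, field_cells = field_cells,
                 field_muni = field_muni, effects = effects,
                 commuting_probs = P, config = config),
            class = "ground_truth")
}

#' Observe a synthetic study from a ground truth
#'
#' Applies the stated observation models: 5-year death counts are Poisson
#' with mean `5 * pop2001 * rate`; origin-destination commuting counts are
#' binomial draws `Binomial(pop2001_i, p_ij)`; monitors record the log cell
#' field plus normal noise; the deterministic-model grid predictions are an
#' affine distortion of the field (`z = slope * field + intercept`) plus a
#' smooth spatial error, so the kriging regression coefficients are
#' identifiable and not trivially (0, 1).  City-level effect estimates (one
#' per capital) are normal around the true capital effects, emulating
#' externally supplied time-series estimates.
#'
#' @param truth a `ground_truth`.
#' @param region the `region_graph` the truth was simulated on.
#' @param n_monitors number of monitors (<= number of grid cells), each
#'   placed inside a distinct grid cell.
#' @param monitor_noise_sd log-scale sd of monitor observation noise.
#' @param seed integer seed.
#' @param grid_distort length-2 numeric `c(intercept, slope)` of the affine
#'   field distortion on the concentration scale.
#' @param grid_error_sd,grid_error_range_km sd (ug/m3) and range of the
#'   smooth spatial error added to grid predictions.
#' @param effect_se standard error attached to emulated city effect
#'   estimates (log RR per ug/m3).
#' @return Object of class `synthetic_study`: list with `region`, `truth`,
#'   `deaths_5yr`, `od_counts`, `monitors` (data.frame: `monitor`, `cell`,
#'   `x`, `y`, `value`), `grid` (region cells plus column `z`), and
#'   `city_effects` (data.frame: `city_id`, `estimate`, `se`).
#' @export
observe_study <- function(truth, region, n_monitors = 12,
                          monitor_noise_sd = 0.05, seed = 1L,
                          grid_distort = c(intercept = 2, slope = 0.9),
                          grid_error_sd = 1.5, grid_error_range_km = 20,
                          effect_se = 3e-4) {
  stopifnot(inherits(truth, "ground_truth"), inherits(region, "region_graph"))
  n_cells <- nrow(region$cells)
  if (n_monitors > n_cells)
    stop("`n_monitors` exceeds the number of grid cells")
  set.seed(seed)
  n <- region$n

  deaths_5yr <- rpois(n, 5 * region$pop2001 * truth$rates)

  P <- truth$commuting_probs
  od_counts <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    pj <- P[i, ]
    pos <- which(pj > 0)
    if (length(pos)) od_counts[i, pos] <- rbinom(length(pos),
                                                 region$pop2001[i], pj[pos])
  }

  mcells <- sort(sample.int(n_cells, n_monitors))
  jit <- matrix(runif(2 * n_monitors, -region$cell_km / 2 + 0.1,
                      region$cell_km / 2 - 0.1), ncol = 2)
  monitors <- data.frame(
    monitor = seq_len(n_monitors), cell = mcells,
    x = region$cells$x[mcells] + jit[, 1],
    y = region$cells$y[mcells] + jit[, 2],
    value = exp(log(truth$field_cells[mcells]) +
                  rnorm(n_monitors, 0, monitor_noise_sd)))

  zerr <- simulate_gp(cbind(region$cells$x, region$cells$y),
                      grid_error_sd, grid_error_range_km)
  grid <- region$cells
  grid$z <- grid_distort[[2]] * truth$field_cells + grid_distort[[1]] + zerr
  grid$z <- pmax(grid$z, 0.1)

  caps <- which(region$capital)
  city_effects <- data.frame(
    city_id = caps,
    estimate = rnorm(length(caps), truth$effects[caps], effect_se),
    se = rep(effect_se, length(caps)))

  structure(list(region = region, truth = truth, deaths_5yr = deaths_5yr,
                 od_counts = od_counts, monitors = monitors, grid = grid,
                 city_effects = city_effects),
            class = "synthetic_study")
}

#' One-call synthetic study at the desk-scale defaults
#'
#' Convenience wrapper: lattice region, ground truth and observed study in
#' one call, with sub-seeds derived from `seed`.
#'
#' @param side lattice side (default 7: 49 municipalities).
#' @param cells_per_muni cells per municipality (default 4).
#' @param n_monitors monitors (default 12).
#' @param seed master seed.
#' @param config a [truth_config()].
#' @param ... passed to [observe_study()].
#' @return a `synthetic_study`.
#' @export
simulate_study <- function(side = 7, cells_per_muni = 4, n_monitors = 12,
                           seed = 1L, config = truth_config(), ...) {
  seeds <- spawn_seeds(seed, 3)
  region <- make_lattice_region(side, cells_per_muni, seed = seeds[1])
  truth <- simulate_truth(region, config, seed = seeds[2])
  observe_study(truth, region, n_monitors = n_monitors, seed = seeds[3], ...)
}

# Independent sub-seeds from a master seed (kept < 2^31).
spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
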