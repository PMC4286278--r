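# Plain-CSV readers/writers for the study exchange format.  All files are
# UTF-8 CSV with a header row; the adjacency file is an undirected edge list
# stored once per edge (i < j); the O-D file omits zero counts.

#' Write a synthetic study to a directory of CSV files
#'
#' Emits `municipalities.csv`, `adjacency.csv`, `od.csv`, `monitors.csv`,
#' `grid.csv`, `truth.csv` and `city_effects.csv`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reg <- study$region
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)

  wr(data.frame(id = seq_len(reg$n), province = reg$province,
                capital = as.integer(reg$capital),
                pop2001 = reg$pop2001, pop2007 = reg$pop2007,
                deaths5yr = study$deaths_5yr,
                centroid_x_km = reg$centroids[, 1],
                centroid_y_km = reg$centroids[, 2]),
     "municipalities.csv")

  edges <- do.call(rbind, lapply(seq_len(reg$n), function(i) {
    nb <- reg$adjacency[[i]]
    nb <- nb[nb > i]
    if (length(nb)) data.frame(from = i, to = nb) else NULL
  }))
  wr(edges, "adjacency.csv")

  idx <- which(study$od_counts > 0, arr.ind = TRUE)
  od <- data.frame(origin = idx[, 1], destination = idx[, 2],
                   count = study$od_counts[idx])
  od <- od[order(od$origin, od$destination), , drop = FALSE]
  wr(od, "od.csv")

  wr(study$monitors, "monitors.csv")
  wr(study$grid, "grid.csv")
  wr(data.frame(id = seq_len(reg$n), true_rate = study$truth$rates,
                true_pm10 = study$truth$field_muni,
                true_effect = study$truth$effects),
     "truth.csv")
  wr(study$city_effects, "city_effects.csv")
  invisible(dir)
}

#' Read a study back from a directory written by [write_study()]
#'
#' Reconstructs the `region_graph` and the observed tables.  The ground
#' truth is reattached when `truth.csv` is present (municipality-level
#' fields only; cell-level truth is not round-tripped).
#'
#' @param dir directory containing the CSV files.
#' @return a list with elements `region`, `deaths_5yr`, `od_counts`,
#'   `monitors`, `grid`, `city_effects` and (if available) `truth_muni`.
#' @export
read_study <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f))
  mun <- rd("municipalities.csv")
  n <- nrow(mun)
  edges <- rd("adjacency.csv")
  adjacency <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]
    adjacency[[i]] <- c(adjacency[[i]], j)
    adjacency[[j]] <- c(adjacency[[j]], i)
  }
  adjacency <- lapply(adjacency, sort)
  grid <- rd("grid.csv")
  region <- structure(list(
    n = n, pop2001 = mun$pop2001, pop2007 = mun$pop2007,
    adjacency = adjacency,
    centroids = cbind(x = mun$centroid_x_km, y = mun$centroid_y_km),
    province = mun$province, capital = as.logical(mun$capital),
    cells = grid[c("cell", "muni", "x", "y")],
    side = as.integer(round(sqrt(n))),
    cells_per_muni = as.integer(nrow(grid) / n), cell_km = 4),
    class = "region_graph")

  od <- rd("od.csv")
  od_counts <- matrix(0L, n, n)
  if (nrow(od)) od_counts[cbind(od$origin, od$destination)] <- od$count

  out <- list(region = region, deaths_5yr = mun$deaths5yr,
              od_counts = od_counts, monitors = rd("monitors.csv"),
              grid = grid, city_effects = rd("city_effects.csv"))
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) out$truth_muni <- read.csv(tf)
  out
}

#' Write posterior draws in long format
#'
#' Long CSV with columns `draw`, `municipality_id` and the value column
#' named by `value_name` -- the exchange format between pipeline stages.
#'
#' @param draws n_draws x n_munis matrix.
#' @param path output CSV path.
#' @param value_name name of the value column (e.g. `"rate"`, `"pm10"`,
#'   `"beta"`).
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path, value_name = "value") {
  df <- data.frame(draw = rep(seq_len(nrow(draws)), ncol(draws)),
                   municipality_id = rep(seq_len(ncol(draws)),
                                         each = nrow(draws)),
                   value = as.vector(draws))
  names(df)[3] <- value_name
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path CSV path.
#' @return n_draws x n_munis matrix.
#' @export
read_draws <- function(path) {
  df <- read.csv(path)
  n_draws <- max(df$draw)
  n <- max(df$municipality_id)
  m <- matrix(NA_real_, n_draws, n)
  m[cbind(df$draw, df$municipality_id)] <- df[[3]]
  m
}
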