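# shared in-code fixtures: tiny grids, affiliation tables, census series

# ramp grid: value = base + col_step*(col-1) + row_step*(row-1)
ramp_grid <- function(ncols = 10, nrows = 10, base = 10, col_step = 1,
                      row_step = 0, origin = c(0, 0), cell_size = 1,
                      variable = "MAT") {
  v <- outer(seq_len(nrows) - 1, seq_len(ncols) - 1,
             function(r, c) base + col_step * c + row_step * r)
  climate_grid(v, origin = origin, cell_size = cell_size, variable = variable)
}

const_grid <- function(value = 17.3, ncols = 5, nrows = 5,
                       origin = c(0, 0), cell_size = 1) {
  climate_grid(matrix(value, nrows, ncols), origin = origin,
               cell_size = cell_size, variable = "MAT")
}

# affiliation table straight from optima
aff_table <- function(species, t_opt, included = TRUE, p_opt = NA_real_) {
  data.frame(species = species, t_opt = t_opt, p_opt = p_opt,
             n_records = 999L, niche_breadth_t = 1,
             included = included)
}

# census series from per-census named stem lists:
# toy_series(list(c1 = data.frame(tag, species, diameter, alive), ...))
toy_series <- function(censuses, dates = NULL, plot_id = "P1", ...) {
  if (is.null(dates)) dates <- seq_along(censuses) * 5 + 2000
  stems <- do.call(rbind, lapply(seq_along(censuses), function(i) {
    s <- censuses[[i]]
    if (!"alive" %in% names(s)) s$alive <- TRUE
    if (!"diameter" %in% names(s)) s$diameter <- 20
    s$census <- i
    s
  }))
  census_series(plot_id, dates, stems, ...)
}

# the worked two-species plot used in several tests:
# first census A x2 (opt 10) + B x2 (opt 20); one A dies, one B recruits
worked_partition_series <- function() {
  toy_series(list(
    data.frame(tag = c("A1", "A2", "B1", "B2"),
               species = c("spA", "spA", "spB", "spB"),
               diameter = 20, alive = TRUE),
    data.frame(tag = c("A1", "A2", "B1", "B2", "B3"),
               species = c("spA", "spA", "spB", "spB", "spB"),
               diameter = 20, alive = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  ), dates = c(2000, 2010))
}

# random occurrence cloud on a grid (uniform over cells)
random_occ <- function(n, grid, species = "sp1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- ncol(grid$values); nr <- nrow(grid$values)
  data.frame(
    species = sample(species, n, replace = TRUE),
    lon = grid$origin[1] + runif(n, 0, nc * grid$cell_size),
    lat = grid$origin[2] + runif(n, 0, nr * grid$cell_size),
    year = sample(1950:2020, n, replace = TRUE),
    flagged = FALSE)
}

# independent oracle: exact signed-rank null distribution by full
# enumeration of the 2^n sign assignments
enum_wilcoxon <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(V = v_obs, p = min(p, 1))
}

# small, fast simulator config for tests
small_sim <- function(seed, ...) {
  args <- list(...)
  base <- list(seed = seed, n_plots = 4, n_species = 20, stems_init = 60,
               census_dates = c(2010, 2016, 2022), occ_per_species = 40,
               grid_ncols = 100, grid_nrows = 20, heights_per_plot = 30)
  base[names(args)] <- args
  do.call(sim_config, base)
}
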