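#' Configuration of the demographic simulator
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' emulating a three-region Afromontane plot network: 17 one-hectare
#' plots spanning a montane temperature gradient, ~560 stems per plot,
#' three censuses over twelve years, slow background demography, and
#' moderately broad species thermal niches. The thermal biases are the
#' signal knobs: `b_r` shifts recruitment (log-scale weight per deg C of
#' species optimum) towards warm-affiliated species, `b_m` raises the
#' mortality odds of species whose optima are cooler than the plot's
#' temperature. Both default to small positive values so a default run
#' exhibits thermophilization driven by recruitment and mortality
#' together; set both to 0 for a null community.
#'
#' @param seed integer root seed; all randomness flows from it.
#' @param n_plots number of plots.
#' @param n_species size of the regional species pool.
#' @param plot_mat_range deg C range of plot mean annual temperature,
#'   plots spaced evenly across it (the elevation gradient).
#' @param niche_sigma_range deg C range of per-species niche widths
#'   (drawn uniformly).
#' @param niche_mu_pad deg C by which species optima may overshoot the
#'   plot MAT range on either side.
#' @param stems_init initial live stems per plot.
#' @param census_dates decimal years of the censuses (>= 2, increasing).
#' @param m0 baseline annual mortality probability.
#' @param r0 recruitment rate, stems per ha per year.
#' @param b_r thermal recruitment bias (per deg C of species optimum).
#' @param b_m thermal mortality bias (per deg C of optimum-minus-plot
#'   temperature mismatch).
#' @param growth_mean,growth_sd among-stem annual diameter increment mean
#'   and SD, cm per year (species-independent by default).
#' @param growth_topt_cor optional slope adding
#'   `growth_topt_cor * (mu_s - mean mu)` to a stem's mean increment, to
#'   emulate warm-affiliated recruits growing faster.
#' @param diam_mean_excess mean of the truncated-exponential initial
#'   diameter distribution above the 10 cm threshold (reverse-J size
#'   structure); the `large_stem` preset adds a heavy-diameter tail.
#' @param large_stem_fraction fraction of initial stems drawn from a
#'   large-diameter (>= 70 cm) component, emulating the dominance of
#'   large stems in Afromontane structure (default 0, i.e. off).
#' @param occ_per_species occurrence records generated per species.
#' @param occ_flagged_frac fraction of occurrence records carrying a
#'   provider-side coordinate flag.
#' @param occ_nodata_frac fraction of occurrence records placed on nodata
#'   (water) cells.
#' @param grid_ncols,grid_nrows,grid_mat_range,grid_map_range,grid_cell_size
#'   climate-grid geometry passed to [generate_climate_grid()].
#' @param heights_per_plot stems per plot given a measured height at the
#'   last census.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_plots = 17,
                       n_species = 60,
                       plot_mat_range = c(8, 20),
                       niche_sigma_range = c(2, 4),
                       niche_mu_pad = 2,
                       stems_init = 560,
                       census_dates = c(2010.5, 2016.5, 2022.5),
                       m0 = 0.009,
                       r0 = 7,
                       b_r = 0.03,
                       b_m = 0.02,
                       growth_mean = 0.18,
                       growth_sd = 0.10,
                       growth_topt_cor = 0,
                       diam_mean_excess = 12.5,
                       large_stem_fraction = 0,
                       occ_per_species = 90,
                       occ_flagged_frac = 0.02,
                       occ_nodata_frac = 0.02,
                       grid_ncols = 200,
                       grid_nrows = 40,
                       grid_mat_range = c(5, 25),
                       grid_map_range = c(800, 2600),
                       grid_cell_size = 1 / 120,
                       heights_per_plot = 60) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_plots >= 1, cfg$n_species >= 1,
    length(cfg$census_dates) >= 2, all(diff(cfg$census_dates) > 0),
    cfg$m0 >= 0, cfg$m0 <= 1, cfg$r0 >= 0,
    all(cfg$niche_sigma_range > 0),
    cfg$occ_flagged_frac >= 0, cfg$occ_flagged_frac <= 1,
    cfg$large_stem_fraction >= 0, cfg$large_stem_fraction <= 1
  )
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed per named stage, kept below 2^31
stage_seed <- function(seed, stage) {
  offs <- c(pool = 11L, grid = 23L, occurrences = 37L, census = 53L,
            heights = 71L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage, call. = FALSE)
  (as.integer(seed) %% 20000000L) * 101L + offs[[stage]]
}

#' Deterministic synthetic climate grids
#'
#' Builds a MAT/MAP grid pair on a lapse-rate ramp: temperature decreases
#' linearly column by column along the grid's x axis (the synthetic
#' elevation axis) from `mat_range[2]` down to `mat_range[1]`, and
#' precipitation increases along the same axis. A few "lake" columns of
#' nodata cells are punched out in symmetric column pairs (so the grid
#' mean is unaffected) to exercise occurrence cleaning. Fully
#' deterministic: no random number is drawn.
#'
#' @param ncols,nrows grid dimensions.
#' @param mat_range,map_range value ranges of the two ramps.
#' @param cell_size cell edge, degrees.
#' @param origin lon/lat of the south-west grid edge.
#' @param n_lake_pairs number of symmetric nodata column pairs (each pair
#'   masks 3 rows of both columns).
#' @return list with elements `mat` and `map`, both [climate_grid]s.
#' @export
generate_climate_grid <- function(ncols = 200, nrows = 40,
                                  mat_range = c(5, 25),
                                  map_range = c(800, 2600),
                                  cell_size = 1 / 120,
                                  origin = c(29, -3),
                                  n_lake_pairs = 2) {
  ramp <- function(rng, decreasing) {
    v <- seq(rng[1], rng[2], length.out = ncols)
    if (decreasing) v <- rev(v)
    matrix(v, nrow = nrows, ncol = ncols, byrow = TRUE)
  }
  mat_v <- ramp(mat_range, decreasing = TRUE) # warm west, cool east: MAT
  map_v <- ramp(map_range, decreasing = FALSE) # falls with "elevation" axis
  if (n_lake_pairs > 0) {
    for (p in seq_len(n_lake_pairs)) {
      j <- round(ncols * 0.25) + 2L * p
      rows <- (2L + p):(4L + p)
      for (col in c(j, ncols + 1L - j)) {
        mat_v[rows, col] <- NA_real_
        map_v[rows, col] <- NA_real_
      }
    }
  }
  list(mat = climate_grid(mat_v, origin, cell_size, "MAT"),
       map = climate_grid(map_v, origin, cell_size, "MAP"))
}

#' Synthetic regional species pool with known thermal niches
#'
#' Draws `n_species` species with Gaussian thermal niches - optimum
#' `mu_s` uniform over the padded plot temperature range, width `sigma_s`
#' uniform over `niche_sigma_range` - plus wood density, maximum height
#' and light guild for trait matching, and a correlated precipitation
#' optimum. Species are binomials distributed over a small set of
#' invented genera and families so taxonomic fallback matching can be
#' exercised.
#'
#' @param config a [sim_config].
#' @return data.frame `species`, `genus`, `family`, `mu`, `sigma`,
#'   `p_mu`, `wood_density`, `max_height`, `light_guild`.
#' @export
generate_species_pool <- function(config) {
  set.seed(stage_seed(config$seed, "pool"))
  n <- config$n_species
  genera <- sprintf("Synthogenus%02d", 1:12)
  families <- sprintf("Synthaceae%02d", 1:5)
  genus <- sample(genera, n, replace = TRUE)
  fam_map <- stats::setNames(sample(families, length(genera), replace = TRUE),
                             genera)
  mu_rng <- config$plot_mat_range + c(-1, 1) * config$niche_mu_pad
  mu <- stats::runif(n, mu_rng[1], mu_rng[2])
  sigma <- stats::runif(n, config$niche_sigma_range[1],
                        config$niche_sigma_range[2])
  # precipitation optimum follows the grid's MAT-MAP coupling plus noise
  p_mu <- stats::approx(config$grid_mat_range, rev(config$grid_map_range),
                        xout = mu, rule = 2)$y + stats::rnorm(n, 0, 100)
  data.frame(
    species = paste0(genus, " sp", sprintf("%03d", seq_len(n))),
    genus = genus, family = unname(fam_map[genus]),
    mu = mu, sigma = sigma, p_mu = p_mu,
    wood_density = pmin(1.1, pmax(0.2, stats::rnorm(n, 0.6, 0.12))),
    max_height = stats::runif(n, 15, 50),
    light_guild = sample(0:3, n, replace = TRUE,
                         prob = c(0.05, 0.2, 0.35, 0.4))
  )
}

#' Species-level trait table from a synthetic pool
#'
#' Emits a trait table in the format of [read_traits()]: species-level
#' rows for most of the pool, with a configurable fraction withheld so
#' genus/family fallback matching is exercised, plus genus- and
#' family-level aggregate rows.
#'
#' @param pool from [generate_species_pool()].
#' @param species_coverage fraction of species given their own row.
#' @return trait data.frame (`taxon`, `level`, `wood_density`,
#'   `max_height`, `light_guild`, `family`).
#' @export
pool_traits <- function(pool, species_coverage = 0.9) {
  n_keep <- max(1, round(nrow(pool) * species_coverage))
  keep <- pool[seq_len(n_keep), , drop = FALSE]
  sp_rows <- data.frame(taxon = keep$species, level = "species",
                        wood_density = keep$wood_density,
                        max_height = keep$max_height,
                        light_guild = keep$light_guild,
                        family = keep$family)
  gen <- stats::aggregate(wood_density ~ genus + family, pool, mean)
  gen_rows <- data.frame(taxon = gen$genus, level = "genus",
                         wood_density = gen$wood_density,
                         max_height = NA_real_, light_guild = 0L,
                         family = gen$family)
  fam <- stats::aggregate(wood_density ~ family, pool, mean)
  fam_rows <- data.frame(taxon = fam$family, level = "family",
                         wood_density = fam$wood_density,
                         max_height = NA_real_, light_guild = 0L,
                         family = fam$family)
  rbind(sp_rows, gen_rows, fam_rows)
}

#' Synthetic occurrence records from known niches
#'
#' For each species, target temperatures are drawn from its Gaussian
#' niche `Normal(mu_s, sigma_s)` truncated to the grid's temperature
#' support, each draw is placed in the grid column whose MAT ramp value
#' is nearest, at a random row and a random position inside the cell.
#' A configured fraction of records is flagged (provider coordinate
#' issue) and another fraction displaced onto nodata lake cells, so the
#' cleaning steps have something to remove. Years are uniform over
#' 1950-2022.
#'
#' @param pool species pool from [generate_species_pool()].
#' @param grids grid pair from [generate_climate_grid()].
#' @param config a [sim_config] (uses the `occ_*` fields and seed).
#' @return occurrence data.frame (`species`, `lon`, `lat`, `year`,
#'   `flagged`).
#' @export
generate_occurrences <- function(pool, grids, config) {
  set.seed(stage_seed(config$seed, "occurrences"))
  g <- grids$mat
  ncols <- ncol(g$values); nrows <- nrow(g$values)
  col_mat <- g$values[1, ] # ramp: columns are constant over rows
  # representative non-NA value per column (lakes only mask some rows)
  col_mat <- apply(g$values, 2, function(v) v[which(!is.na(v))[1]])
  lake <- which(is.na(g$values))
  n_per <- config$occ_per_species
  rows <- lapply(seq_len(nrow(pool)), function(i) {
    tgt <- stats::rnorm(n_per, pool$mu[i], pool$sigma[i])
    tgt <- pmin(max(col_mat, na.rm = TRUE), pmax(min(col_mat, na.rm = TRUE), tgt))
    col <- vapply(tgt, function(t) which.min(abs(col_mat - t)), 0L)
    row <- sample.int(nrows, n_per, replace = TRUE)
    # displace a fraction onto lake cells
    n_lake <- stats::rbinom(1, n_per, config$occ_nodata_frac)
    if (n_lake > 0 && length(lake)) {
      pick <- sample(lake, n_lake, replace = TRUE)
      row[seq_len(n_lake)] <- (pick - 1L) %% nrows + 1L
      col[seq_len(n_lake)] <- (pick - 1L) %/% nrows + 1L
    }
    data.frame(
      species = pool$species[i],
      lon = g$origin[1] + (col - 1 + stats::runif(n_per)) * g$cell_size,
      lat = g$origin[2] + (row - 1 + stats::runif(n_per)) * g$cell_size,
      year = sample(1950:2022, n_per, replace = TRUE),
      flagged = stats::runif(n_per) < config$occ_flagged_frac)
  })
  do.call(rbind, rows)
}

# initial diameters: truncated exponential above 10 cm (reverse-J), with an
# optional large-stem component
draw_diameters <- function(n, config) {
  d <- 10 + stats::rexp(n, rate = 1 / config$diam_mean_excess)
  if (config$large_stem_fraction > 0) {
    big <- stats::runif(n) < config$large_stem_fraction
    d[big] <- 70 + stats::rexp(sum(big), rate = 1 / 20)
  }
  d
}

#' Simulate a multi-census plot network with known thermal biases
#'
#' The demographic process, per plot with site temperature `MAT_p`:
#' the initial community samples species with probability proportional to
#' the Gaussian suitability `exp(-(MAT_p - mu_s)^2 / (2 sigma_s^2))`;
#' each census interval of length T, a stem of species s dies with
#' probability `1 - (1 - m_s)^T` where
#' `logit(m_s) = logit(m0) - b_m (mu_s - MAT_p)` (cool-affiliated species
#' die faster when `b_m > 0`); survivors add a Normal annual diameter
#' increment (truncated at zero); and `Poisson(r0 area T)` recruits enter
#' at 10-15 cm with species drawn proportional to
#' `suitability x exp(b_r mu_s)`. The recruitment bias acts on species
#' identity, not on stem counts, so stem density is trend-stationary
#' under the null. Stems that die are recorded once, dead, at their last
#' live diameter; tags never resurrect. At the last census a subsample of
#' stems receives a measured height from a known Weibull height-diameter
#' law with lognormal noise.
#'
#' @param config a [sim_config].
#' @return list of class `sim_bundle`: `series` (named list of
#'   [census_series]), `pool` (species pool = ground-truth optima),
#'   `traits` (via [pool_traits()]), `plots` (data.frame `plot_id`,
#'   `mat`, `lon`, `lat`, `elevation`), `events` (per-plot death/recruit
#'   counts), `config`.
#' @export
simulate_census_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pool <- generate_species_pool(config)
  grids <- generate_climate_grid(
    config$grid_ncols, config$grid_nrows, config$grid_mat_range,
    config$grid_map_range, config$grid_cell_size)
  set.seed(stage_seed(config$seed, "census"))

  plot_mat <- if (config$n_plots == 1) mean(config$plot_mat_range) else
    seq(config$plot_mat_range[1], config$plot_mat_range[2],
        length.out = config$n_plots)
  # plot coordinates: centre of the ramp column nearest the plot's MAT
  col_mat <- apply(grids$mat$values, 2, function(v) v[which(!is.na(v))[1]])
  dates <- config$census_dates
  k <- length(dates)

  series <- list()
  events <- list()
  for (p in seq_len(config$n_plots)) {
    pid <- sprintf("PLOT%02d", p)
    matp <- plot_mat[p]
    colp <- which.min(abs(col_mat - matp))
    suit <- exp(-(matp - pool$mu)^2 / (2 * pool$sigma^2))
    rec_w <- suit * exp(config$b_r * pool$mu)
    n0 <- config$stems_init
    sp_idx <- sample.int(nrow(pool), n0, replace = TRUE, prob = suit)
    live <- data.frame(
      tag = sprintf("%s-%05d", pid, seq_len(n0)),
      sp = sp_idx, diameter = draw_diameters(n0, config))
    next_tag <- n0 + 1
    m_s <- stats::plogis(stats::qlogis(config$m0) -
                           config$b_m * (pool$mu - matp))
    g_mu <- config$growth_mean +
      config$growth_topt_cor * (pool$mu - mean(pool$mu))

    rows <- list(data.frame(
      tag = live$tag, species = pool$species[live$sp], census = 1L,
      diameter = live$diameter, alive = TRUE, height = NA_real_))
    n_deaths <- n_recruits <- 0L
    for (cc in 2:k) {
      T <- dates[cc] - dates[cc - 1]
      p_die <- 1 - (1 - m_s[live$sp])^T
      dies <- stats::runif(nrow(live)) < p_die
      dead <- live[dies, , drop = FALSE]
      live <- live[!dies, , drop = FALSE]
      live$diameter <- live$diameter +
        pmax(0, stats::rnorm(nrow(live), g_mu[live$sp], config$growth_sd)) * T
      n_rec <- stats::rpois(1, config$r0 * T)
      if (n_rec > 0) {
        rsp <- sample.int(nrow(pool), n_rec, replace = TRUE, prob = rec_w)
        rec <- data.frame(
          tag = sprintf("%s-%05d", pid, next_tag - 1 + seq_len(n_rec)),
          sp = rsp, diameter = stats::runif(n_rec, 10, 15))
        next_tag <- next_tag + n_rec
        live <- rbind(live, rec)
      } else {
        rec <- live[0, ]
      }
      n_deaths <- n_deaths + nrow(dead)
      n_recruits <- n_recruits + n_rec
      rows[[cc]] <- rbind(
        data.frame(tag = live$tag, species = pool$species[live$sp],
                   census = cc, diameter = live$diameter, alive = TRUE,
                   height = NA_real_),
        if (nrow(dead)) data.frame(
          tag = dead$tag, species = pool$species[dead$sp], census = cc,
          diameter = dead$diameter, alive = FALSE, height = NA_real_))
    }
    stems <- do.call(rbind, rows)
    # measured heights at the last census from a known Weibull law
    last_live <- which(stems$census == k & stems$alive)
    n_h <- min(config$heights_per_plot, length(last_live))
    if (n_h >= 1) {
      pick <- sample(last_live, n_h)
      dmes <- stems$diameter[pick]
      stems$height[pick] <- 42 * (1 - exp(-(dmes / 28)^0.85)) *
        exp(stats::rnorm(n_h, 0, 0.08))
    }
    cs <- grids$mat$cell_size
    series[[pid]] <- census_series(
      pid, dates, stems,
      lon = grids$mat$origin[1] + (colp - 0.5) * cs,
      lat = grids$mat$origin[2] + (nrow(grids$mat$values) / 2) * cs,
      elevation = 600 + (max(col_mat, na.rm = TRUE) - matp) * 170,
      area_ha = 1)
    events[[pid]] <- data.frame(plot_id = pid, mat = matp,
                                deaths = n_deaths, recruits = n_recruits)
  }
  structure(list(series = series, pool = pool,
                 traits = pool_traits(pool),
                 plots = data.frame(
                   plot_id = names(series),
                   mat = plot_mat,
                   lon = vapply(series, function(s) s$lon, 0),
                   lat = vapply(series, function(s) s$lat, 0),
                   elevation = vapply(series, function(s) s$elevation, 0)),
                 events = do.call(rbind, events),
                 config = config, grids = grids),
            class = "sim_bundle")
}

#' Ground-truth affiliation table of a simulation
#'
#' The generator's own species optima cast in the format of
#' [build_affiliation_table()], for computing realized (truth-based)
#' index trajectories against which pipeline estimates are compared.
#'
#' @param bundle a `sim_bundle` from [simulate_census_series()], or a
#'   species pool data.frame.
#' @return affiliation data.frame with `t_opt = mu`, all species included.
#' @export
true_affiliations <- function(bundle) {
  pool <- if (inherits(bundle, "sim_bundle")) bundle$pool else bundle
  data.frame(species = pool$species, t_opt = pool$mu, p_opt = pool$p_mu,
             n_records = NA_integer_,
             niche_breadth_t = 2 * stats::qnorm(0.95) * pool$sigma,
             included = TRUE)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> %d plots x %d censuses, %d species, seed %d (b_r=%.2g, b_m=%.2g)\n",
    length(x$series), length(x$config$census_dates), nrow(x$pool),
    x$config$seed, x$config$b_r, x$config$b_m))
  invisible(x)
}
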