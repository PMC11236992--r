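#' Clean occurrence records against a climatology grid
#'
#' Applies, in fixed order: (1) removal of provider-flagged records
#' (possible coordinate issues); (2) an optional year cutoff so records are
#' temporally matched with the climatology (records with no year are
#' dropped when a cutoff is active); (3) removal of records falling on
#' nodata cells (large water bodies, outside the climatology domain) or
#' outside the grid entirely. Deduplication is a separate step
#' ([dedupe_by_cell()]) applied after cleaning, so the retained cell
#' representative is always a clean record.
#'
#' @param occ occurrence data.frame (`species`, `lon`, `lat`, `year`,
#'   `flagged`), e.g. from [read_occurrences()].
#' @param grid [climate_grid] providing the domain and nodata mask.
#' @param since optional integer year; keep only records with
#'   `year >= since`.
#' @return filtered data.frame; `attr(, "n_removed")` gives counts per step.
#' @export
clean_occurrences <- function(occ, grid, since = NULL) {
  n0 <- nrow(occ)
  occ <- occ[!occ$flagged, , drop = FALSE]
  n_flag <- n0 - nrow(occ)
  n_year <- 0L
  if (!is.null(since)) {
    keep <- !is.na(occ$year) & occ$year >= since
    n_year <- sum(!keep)
    occ <- occ[keep, , drop = FALSE]
  }
  vals <- extract_climate(grid, occ$lon, occ$lat)
  n_nodata <- sum(is.na(vals))
  occ <- occ[!is.na(vals), , drop = FALSE]
  attr(occ, "n_removed") <- c(flagged = n_flag, year = n_year,
                              nodata = n_nodata)
  occ
}

#' Discard duplicate records per species per grid cell
#'
#' At most one record per species per climatology grid cell is kept (the
#' first in file order), so densely collected localities do not dominate a
#' species' climate affiliation. Deduplication is per species: records of
#' different species in the same cell are all retained. Idempotent.
#'
#' @inheritParams clean_occurrences
#' @return deduplicated data.frame.
#' @export
dedupe_by_cell <- function(occ, grid) {
  if (!nrow(occ)) return(occ)
  key <- paste(occ$species, cell_index(grid, occ$lon, occ$lat), sep = "\r")
  occ[!duplicated(key), , drop = FALSE]
}

#' Climate optimum of one species
#'
#' The species' optimum for the grid's variable is the arithmetic mean of
#' the cell values at its (cleaned, deduplicated) occurrence locations.
#'
#' @param occ occurrence records of a single species.
#' @param grid [climate_grid] to score against.
#' @return list with `optimum` (NA when no usable record) and `n_records`.
#' @export
species_optimum <- function(occ, grid) {
  vals <- extract_climate(grid, occ$lon, occ$lat)
  vals <- vals[!is.na(vals)]
  list(optimum = if (length(vals)) mean(vals) else NA_real_,
       n_records = length(vals))
}

#' Climatic niche breadth of one species
#'
#' Breadth is the difference between the 95th and 5th percentile of the
#' climate values at the species' occurrence locations, under the
#' linear-interpolation quantile convention (`stats::quantile` type 7,
#' h = (n-1)p + 1). Needs at least two usable records.
#'
#' @inheritParams species_optimum
#' @return breadth in the grid variable's units, or `NA`.
#' @export
niche_breadth <- function(occ, grid) {
  vals <- extract_climate(grid, occ$lon, occ$lat)
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) return(NA_real_)
  unname(diff(stats::quantile(vals, c(0.05, 0.95), type = 7)))
}

#' Optimum error as a function of record count
#'
#' Quantifies how the estimate of a species' climate optimum degrades with
#' fewer occurrence records: for each subsample size n, records are drawn
#' without replacement, the subsampled optimum computed, and the mean
#' absolute deviation from the full-record optimum reported over
#' replicates. Plotted over n, such curves typically show an inflection
#' near 10 records, motivating a minimum-record inclusion threshold; the
#' choice of threshold is left to the caller.
#'
#' @param occ occurrence records of a single species (cleaned, deduped).
#' @param grid [climate_grid].
#' @param sizes integer subsample sizes; sizes exceeding the number of
#'   usable records are skipped with a warning.
#' @param replicates subsample replicates per size (default 100).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame `n`, `mae`, `replicates`; attribute `full_optimum`.
#' @export
threshold_error_curve <- function(occ, grid, sizes = c(5, 10, 20, 30, 50),
                                  replicates = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- extract_climate(grid, occ$lon, occ$lat)
  vals <- vals[!is.na(vals)]
  n_rec <- length(vals)
  if (n_rec < 2) stop("need at least 2 usable records", call. = FALSE)
  full <- mean(vals)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes > n_rec)) {
    warning("skipping subsample sizes exceeding the ", n_rec,
            " available records", call. = FALSE)
    sizes <- sizes[sizes <= n_rec]
  }
  mae <- vapply(sizes, function(n) {
    if (n == n_rec) return(0) # full sample reproduces the full optimum
    mean(vapply(seq_len(replicates), function(i) {
      abs(mean(sample(vals, n)) - full)
    }, 0))
  }, 0)
  out <- data.frame(n = sizes, mae = mae, replicates = replicates)
  attr(out, "full_optimum") <- full
  attr(out, "seed") <- seed
  out
}

resolve_threshold <- function(threshold) {
  if (is.character(threshold)) {
    threshold <- switch(threshold,
      none = 0L, standard = 10L, strict = 30L,
      stop("unknown threshold preset: ", threshold, call. = FALSE))
  }
  as.integer(threshold)
}

#' Build the species affiliation table
#'
#' Runs the whole occurrence-scoring chain for every species in a pooled
#' occurrence table: cleaning and per-cell deduplication against the
#' temperature grid, then per species the thermal optimum (mean MAT at
#' occurrence locations), precipitation optimum (mean MAP at the same
#' retained records), record count, thermal niche breadth (95th minus 5th
#' MAT percentile), and an inclusion flag `n_records >= threshold`.
#'
#' @param occ pooled occurrence data.frame.
#' @param grid_t MAT [climate_grid] (also defines cleaning/dedup cells).
#' @param grid_p MAP [climate_grid], or `NULL` to skip `p_opt`.
#' @param threshold minimum record count for inclusion: an integer or one
#'   of the presets `"none"` (0), `"standard"` (10), `"strict"` (30).
#' @param since optional year cutoff passed to [clean_occurrences()].
#' @return data.frame with one row per species: `species`, `t_opt`,
#'   `p_opt`, `n_records`, `niche_breadth_t`, `included`.
#' @export
build_affiliation_table <- function(occ, grid_t, grid_p = NULL,
                                    threshold = 10, since = NULL) {
  threshold <- resolve_threshold(threshold)
  occ <- clean_occurrences(occ, grid_t, since = since)
  occ <- dedupe_by_cell(occ, grid_t)
  sp <- sort(unique(occ$species))
  rows <- lapply(sp, function(s) {
    rec <- occ[occ$species == s, , drop = FALSE]
    opt_t <- species_optimum(rec, grid_t)
    p_opt <- if (is.null(grid_p)) NA_real_ else {
      pv <- extract_climate(grid_p, rec$lon, rec$lat)
      if (any(!is.na(pv))) mean(pv, na.rm = TRUE) else NA_real_
    }
    data.frame(species = s, t_opt = opt_t$optimum, p_opt = p_opt,
               n_records = opt_t$n_records,
               niche_breadth_t = niche_breadth(rec, grid_t),
               included = opt_t$n_records >= threshold)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(), t_opt = numeric(),
                      p_opt = numeric(), n_records = integer(),
                      niche_breadth_t = numeric(), included = logical())
  }
  attr(out, "threshold") <- threshold
  attr(out, "since") <- since
  out
}
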