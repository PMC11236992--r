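#' Read a long-format census table
#'
#' Reads a CSV with one row per stem per census and assembles one
#' [census_series] per plot. Required columns: `plot_id`, `tag`, `species`,
#' `census_date` (decimal years), `diameter_cm`, `alive` (logical or 0/1).
#' Optional: `height_m`, `lon`, `lat`, `elevation_m`, `area_ha` (plot-level,
#' repeated per row). Stems identified only to genus or family should carry
#' a non-binomial sentinel ID (e.g. `"Macaranga indet."` or `"indet"`);
#' they are read verbatim and excluded later by attribute matching.
#'
#' Rows violating record-level invariants (live stem under the minimum
#' diameter, unparseable fields, a tag recorded alive after dead) are
#' rejected, not silently dropped: the returned object carries a
#' line-numbered report in `attr(, "rejected")`, and
#' `accepted + rejected = input rows` always holds.
#'
#' @param path CSV path.
#' @param min_diameter census protocol diameter threshold, cm (default 10).
#' @return named list of [census_series], one per plot, with attributes
#'   `rejected` (data.frame `line`, `tag`, `reason`) and `n_input`.
#' @export
read_census_table <- function(path, min_diameter = 10) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "tag", "species", "census_date", "diameter_cm", "alive")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("census table ", path, " lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(raw)
  raw$.line <- seq_len(n_input) + 1L # header is line 1
  raw$alive <- as.logical(raw$alive)
  raw$census_date <- as.numeric(raw$census_date)
  raw$diameter_cm <- as.numeric(raw$diameter_cm)

  rej <- data.frame(line = integer(), tag = character(), reason = character())
  reject <- function(rows, reason) {
    if (!nrow(rows)) return()
    rej <<- rbind(rej, data.frame(line = rows$.line, tag = as.character(rows$tag),
                                  reason = reason))
  }

  bad_parse <- is.na(raw$alive) | is.na(raw$census_date) | is.na(raw$diameter_cm) |
    !nzchar(raw$tag) | !nzchar(raw$plot_id)
  reject(raw[bad_parse, , drop = FALSE], "unparseable or empty required field")
  raw <- raw[!bad_parse, , drop = FALSE]

  small <- raw$alive & raw$diameter_cm < min_diameter
  reject(raw[small, , drop = FALSE],
         sprintf("live stem below %g cm diameter", min_diameter))
  raw <- raw[!small, , drop = FALSE]

  out <- list()
  for (pid in unique(raw$plot_id)) {
    pr <- raw[raw$plot_id == pid, , drop = FALSE]
    dates <- sort(unique(pr$census_date))
    pr$census <- match(pr$census_date, dates)
    # resurrection: reject the offending alive-after-dead rows, keep the rest
    pr <- pr[order(pr$tag, pr$census), , drop = FALSE]
    repeat {
      res <- resurrected_tags(data.frame(tag = pr$tag, census = pr$census,
                                         alive = pr$alive))
      if (!length(res)) break
      first_dead <- tapply(ifelse(pr$alive, Inf, pr$census), pr$tag, min)
      bad <- pr$tag %in% res & pr$alive &
        pr$census > first_dead[as.character(pr$tag)]
      reject(pr[bad, , drop = FALSE],
             sprintf("tag recorded alive after dead"))
      pr <- pr[!bad, , drop = FALSE]
    }
    stems <- data.frame(
      tag = as.character(pr$tag), species = as.character(pr$species),
      census = pr$census, diameter = pr$diameter_cm, alive = pr$alive,
      height = if ("height_m" %in% names(pr)) as.numeric(pr$height_m) else NA_real_
    )
    grab <- function(col) {
      if (col %in% names(pr) && length(v <- unique(pr[[col]][!is.na(pr[[col]])]))) {
        v[1]
      } else NA_real_
    }
    area <- grab("area_ha"); if (is.na(area)) area <- 1
    out[[pid]] <- census_series(
      pid, dates, stems,
      lon = grab("lon"), lat = grab("lat"),
      elevation = grab("elevation_m"), area_ha = area
    )
  }
  stopifnot(sum(vapply(out, function(s) nrow(s$stems), 0L)) + nrow(rej) == n_input)
  attr(out, "rejected") <- rej
  attr(out, "n_input") <- n_input
  out
}

#' Write census series back to the long CSV format
#'
#' Inverse of [read_census_table()]: writing and re-reading a valid
#' collection reproduces identical content.
#'
#' @param series_list a [census_series] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(series_list, path) {
  if (inherits(series_list, "census_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    st <- s$stems
    data.frame(
      plot_id = s$plot_id, tag = st$tag, species = st$species,
      census_date = s$census_dates[st$census],
      diameter_cm = st$diameter, alive = st$alive, height_m = st$height,
      lon = s$lon, lat = s$lat, elevation_m = s$elevation, area_ha = s$area_ha
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read species occurrence records
#'
#' Parses a Darwin-Core-style CSV export with columns `species`,
#' `decimalLongitude`, `decimalLatitude` and optional `year` and `issue`
#' (non-empty issue text marks a provider-side coordinate flag). Rows with
#' unparseable or out-of-range coordinates are rejected and counted, never
#' silently dropped.
#'
#' @param path CSV path.
#' @return data.frame with columns `species`, `lon`, `lat`, `year`,
#'   `flagged`; attributes `n_input` and `n_rejected`.
#' @export
read_occurrences <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "decimalLongitude", "decimalLatitude")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("occurrence table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(raw$decimalLongitude))
  lat <- suppressWarnings(as.numeric(raw$decimalLatitude))
  ok <- !is.na(lon) & !is.na(lat) & lon >= -180 & lon <= 180 &
    lat >= -90 & lat <= 90 & nzchar(raw$species)
  out <- data.frame(
    species = as.character(raw$species[ok]),
    lon = lon[ok], lat = lat[ok],
    year = if ("year" %in% names(raw)) {
      suppressWarnings(as.integer(raw$year[ok]))
    } else NA_integer_,
    flagged = if ("issue" %in% names(raw)) {
      !is.na(raw$issue[ok]) & nzchar(raw$issue[ok])
    } else FALSE
  )
  attr(out, "n_input") <- nrow(raw)
  attr(out, "n_rejected") <- nrow(raw) - nrow(out)
  out
}

#' @rdname read_occurrences
#' @param occ occurrence data.frame as returned by `read_occurrences()`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(
    data.frame(species = occ$species, decimalLongitude = occ$lon,
               decimalLatitude = occ$lat, year = occ$year,
               issue = ifelse(occ$flagged, "COORDINATE_ROUNDED", "")),
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a species trait table
#'
#' Trait rows can sit at species, genus, or family level (column `level`);
#' `taxon` holds the name at that level. Columns: `taxon`, `level`,
#' `wood_density` (g cm^-3), optional `max_height` (m), `light_guild`
#' (0 no data, 1 pioneer light demander, 2 non-pioneer light demander,
#' 3 shade bearer) and `family` (the family of a species/genus row, used
#' for the family-level fallback in wood-density matching).
#'
#' @param path CSV path.
#' @return validated data.frame of trait rows.
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "level", "wood_density")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("trait table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tr$level %in% c("species", "genus", "family"))) {
    stop("trait `level` must be species/genus/family", call. = FALSE)
  }
  if (any(!is.na(tr$wood_density) & tr$wood_density <= 0)) {
    stop("wood_density must be positive", call. = FALSE)
  }
  if ("light_guild" %in% names(tr) &&
      !all(is.na(tr$light_guild) | tr$light_guild %in% 0:3)) {
    stop("light_guild must be in 0:3", call. = FALSE)
  }
  if (!"family" %in% names(tr)) tr$family <- NA_character_
  if (!"max_height" %in% names(tr)) tr$max_height <- NA_real_
  if (!"light_guild" %in% names(tr)) tr$light_guild <- 0L
  tr
}

#' Write a species affiliation table
#'
#' @param affiliations data.frame from [build_affiliation_table()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_affiliations <- function(affiliations, path) {
  utils::write.csv(affiliations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_affiliations
#' @export
read_affiliations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
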