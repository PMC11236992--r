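#' Repeated stem inventory for one plot
#'
#' A `census_series` bundles the stem-level repeated measurements of one
#' inventory plot: ordered census dates (decimal years) and a long-format
#' stem table with one row per stem per census in which it was recorded.
#' This is the unit on which all community-index and carbon computations
#' operate. The census protocol emulated here records all stems >= 10 cm
#' diameter at 1.3 m; a stem recorded dead stays dead (no resurrection),
#' and dead stems carry their last live diameter.
#'
#' @param plot_id plot identifier.
#' @param census_dates numeric vector of strictly increasing decimal years.
#' @param stems data.frame with columns `tag`, `species`, `census`
#'   (integer index into `census_dates`), `diameter` (cm), `alive`
#'   (logical), and optionally `height` (m, `NA` when unmeasured).
#' @param lon,lat plot coordinates in decimal degrees (optional).
#' @param elevation plot elevation, m asl (optional).
#' @param area_ha plot area in hectares (default 1).
#' @return An object of class `census_series`.
#' @export
census_series <- function(plot_id, census_dates, stems,
                          lon = NA_real_, lat = NA_real_,
                          elevation = NA_real_, area_ha = 1) {
  stems <- as.data.frame(stems)
  need <- c("tag", "species", "census", "diameter", "alive")
  miss <- setdiff(need, names(stems))
  if (length(miss)) {
    stop("stem table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"height" %in% names(stems)) stems$height <- NA_real_
  stems$census <- as.integer(stems$census)
  obj <- structure(
    list(plot_id = as.character(plot_id),
         census_dates = as.numeric(census_dates),
         stems = stems,
         lon = lon, lat = lat, elevation = elevation,
         area_ha = area_ha),
    class = "census_series"
  )
  problems <- validate_census_series(obj)
  if (length(problems)) {
    stop("invalid census series '", plot_id, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  obj
}

#' Check the structural invariants of a census series
#'
#' Returns a character vector of problems (empty when valid): census dates
#' must strictly increase, stem census indices must reference existing
#' censuses, live stems must be >= 10 cm diameter, and no tag may be
#' recorded alive after being recorded dead.
#'
#' @param x a [census_series] (or a list with the same fields).
#' @param min_diameter minimum diameter for live stems, cm.
#' @return character vector of human-readable problems.
#' @export
validate_census_series <- function(x, min_diameter = 10) {
  p <- character()
  d <- x$census_dates
  if (length(d) < 1 || any(diff(d) <= 0)) {
    p <- c(p, "census dates must be strictly increasing")
  }
  s <- x$stems
  if (nrow(s)) {
    if (any(s$census < 1 | s$census > length(d), na.rm = TRUE)) {
      p <- c(p, "stem rows reference census indices outside the date list")
    }
    und <- s$alive & (is.na(s$diameter) | s$diameter < min_diameter)
    if (any(und, na.rm = TRUE)) {
      p <- c(p, sprintf("live stems below %g cm diameter: tags %s",
                        min_diameter,
                        paste(unique(s$tag[which(und)]), collapse = ", ")))
    }
    res <- resurrected_tags(s)
    if (length(res)) {
      p <- c(p, sprintf("tags recorded alive after dead (resurrection): %s",
                        paste(res, collapse = ", ")))
    }
  }
  p
}

# tags that appear alive at a census after having been recorded dead earlier
resurrected_tags <- function(stems) {
  s <- stems[order(stems$tag, stems$census), ]
  bad <- character()
  dead_since <- tapply(ifelse(s$alive, Inf, s$census), s$tag, min)
  last_alive <- tapply(ifelse(s$alive, s$census, -Inf), s$tag, max)
  res <- names(dead_since)[last_alive > dead_since]
  sort(res)
}

#' @export
print.census_series <- function(x, ...) {
  cat(sprintf("<census_series> plot %s: %d censuses (%s), %d stem records\n",
              x$plot_id, length(x$census_dates),
              paste(format(x$census_dates), collapse = ", "),
              nrow(x$stems)))
  invisible(x)
}

#' Stems recorded at one census
#'
#' @param series a [census_series].
#' @param census census index (1-based); defaults to the first.
#' @param alive_only keep only live stems (default `TRUE`).
#' @return data.frame of stem rows at that census.
#' @export
stems_at <- function(series, census = 1, alive_only = TRUE) {
  s <- series$stems[series$stems$census == census, , drop = FALSE]
  if (alive_only) s <- s[s$alive, , drop = FALSE]
  s
}
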