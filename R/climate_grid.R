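#' Gridded climatology in memory
#'
#' A `climate_grid` holds one climatological variable (mean annual temperature
#' in degrees C, or mean annual precipitation in mm) on a regular
#' longitude-latitude grid, the way ~30 arc-second climatologies distribute
#' it. Cells are half-open in both axes: a cell with lower-left edge
#' `(x0, y0)` contains every point with `x0 <= lon < x0 + cell_size` and
#' `y0 <= lat < y0 + cell_size`, so any in-bounds coordinate falls in exactly
#' one cell.
#'
#' @param values numeric matrix of cell values; row 1 is the southernmost
#'   row, column 1 the westernmost column. `NA` marks nodata (water,
#'   out-of-domain).
#' @param origin numeric length-2, lon/lat of the lower-left (south-west)
#'   edge of the grid.
#' @param cell_size cell edge length in decimal degrees; the default
#'   `1/120` is a 30 arc-second grid.
#' @param variable `"MAT"` or `"MAP"`.
#' @return An object of class `climate_grid`.
#' @examples
#' g <- climate_grid(matrix(17.3, 4, 4), origin = c(30, -2))
#' extract_climate(g, 30.01, -1.99)
#' @export
climate_grid <- function(values, origin = c(0, 0), cell_size = 1 / 120,
                         variable = c("MAT", "MAP")) {
  variable <- match.arg(variable)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (length(origin) != 2 || !is.numeric(origin)) {
    stop("`origin` must be numeric lon/lat of length 2", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = cell_size, variable = variable),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<climate_grid> %s: %d rows x %d cols, cell %.6f deg, origin (%.4f, %.4f)\n",
    x$variable, nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values %.3f .. %.3f, %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

# column/row index of the cell containing each point; NA when out of bounds.
# Half-open convention: index = floor((coord - origin)/cell_size) + 1.
grid_col_row <- function(grid, lon, lat) {
  ix <- floor((lon - grid$origin[1]) / grid$cell_size) + 1
  iy <- floor((lat - grid$origin[2]) / grid$cell_size) + 1
  bad <- ix < 1 | ix > ncol(grid$values) | iy < 1 | iy > nrow(grid$values) |
    is.na(lon) | is.na(lat)
  ix[bad] <- NA_integer_
  iy[bad] <- NA_integer_
  list(col = as.integer(ix), row = as.integer(iy))
}

#' Look up climate values at point coordinates
#'
#' Returns the value of the unique grid cell containing each point. Points
#' on an interior cell edge belong to the cell whose *lower* edge they sit
#' on (half-open cells). Out-of-bounds points and points over nodata cells
#' yield `NA`, so callers can decide whether to drop the record.
#'
#' @param grid a [climate_grid].
#' @param lon,lat numeric vectors of equal length, decimal degrees (WGS84).
#' @return numeric vector of cell values, `NA` where missing.
#' @export
extract_climate <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "climate_grid"))
  if (length(lon) != length(lat)) {
    stop("`lon` and `lat` must have equal length", call. = FALSE)
  }
  idx <- grid_col_row(grid, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx$col)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Linear index of the grid cell containing each point
#'
#' Used to deduplicate occurrence records per cell: two points share an index
#' if and only if they fall in the same cell. `NA` for out-of-bounds points.
#'
#' @inheritParams extract_climate
#' @return integer vector of cell indices (row-major over the grid).
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "climate_grid"))
  idx <- grid_col_row(grid, lon, lat)
  (idx$row - 1L) * ncol(grid$values) + idx$col
}

#' Read and write plain-text climate grids
#'
#' The package's grid interchange format is plain text with a seven-line
#' header (`variable`, `origin_lon`, `origin_lat`, `cell_size`, `ncols`,
#' `nrows`, `nodata`) followed by `nrows` whitespace-separated data rows,
#' northernmost row first (the usual ASCII-raster row order). The nodata
#' sentinel in the file becomes `NA` in memory and vice versa.
#'
#' @param path file path.
#' @return `read_climate_grid()` returns a [climate_grid];
#'   `write_climate_grid()` returns `path` invisibly.
#' @export
read_climate_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 8) stop("climate grid file too short: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1:7]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- vapply(hdr, `[`, "", 2)
  names(val) <- key
  need <- c("variable", "origin_lon", "origin_lat", "cell_size",
            "ncols", "nrows", "nodata")
  if (!all(need %in% key)) {
    stop("climate grid header must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ncols <- as.integer(val[["ncols"]])
  nrows <- as.integer(val[["nrows"]])
  nodata <- as.numeric(val[["nodata"]])
  rows <- lapply(lines[8:(7 + nrows)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (any(lengths(rows) != ncols)) {
    stop("climate grid data rows do not all have ncols = ", ncols, call. = FALSE)
  }
  m <- do.call(rbind, rev(rows)) # file is north-first; memory is south-first
  m[m == nodata] <- NA_real_
  climate_grid(m, origin = as.numeric(val[c("origin_lon", "origin_lat")]),
               cell_size = as.numeric(val[["cell_size"]]),
               variable = val[["variable"]])
}

#' @rdname read_climate_grid
#' @param grid a [climate_grid] to write.
#' @param nodata numeric sentinel written in place of `NA`.
#' @export
write_climate_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "climate_grid"))
  m <- grid$values
  m[is.na(m)] <- nodata
  num <- function(x) sprintf("%.17g", x) # round-trips doubles exactly
  hdr <- c(
    paste("variable", grid$variable),
    paste("origin_lon", num(grid$origin[1])),
    paste("origin_lat", num(grid$origin[2])),
    paste("cell_size", num(grid$cell_size)),
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("nodata", num(nodata))
  )
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1,
                function(r) paste(num(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
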