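#' Define a regular longitude/latitude grid
#'
#' Grids are regular WGS84 lon/lat rasters. Cell centres are the evaluation
#' points for profile scoring; row 1 is the northernmost row (raster
#' convention), column 1 the westernmost column.
#'
#' @param min_lon,max_lon,min_lat,max_lat Bounding box in decimal degrees.
#' @param cell_size Cell edge length in decimal degrees (> 0).
#' @return An object of class `grid_spec` with fields `min_lon`, `max_lon`,
#'   `min_lat`, `max_lat`, `cell_size`, `n_rows`, `n_cols`.
#' @examples
#' g <- grid_spec(14, 15, 40, 41, cell_size = 0.1)
#' g$n_rows # 10
#' @export
grid_spec <- function(min_lon, max_lon, min_lat, max_lat, cell_size) {
  stopifnot(is.numeric(min_lon), is.numeric(max_lon),
            is.numeric(min_lat), is.numeric(max_lat), is.numeric(cell_size))
  if (max_lon <= min_lon) stop("max_lon must exceed min_lon")
  if (max_lat <= min_lat) stop("max_lat must exceed min_lat")
  if (cell_size <= 0) stop("cell_size must be positive")
  check_lonlat(c(min_lon, max_lon), c(min_lat, max_lat))
  n_cols <- max(1L, as.integer(ceiling((max_lon - min_lon) / cell_size - 1e-9)))
  n_rows <- max(1L, as.integer(ceiling((max_lat - min_lat) / cell_size - 1e-9)))
  structure(
    list(min_lon = min_lon, max_lon = max_lon,
         min_lat = min_lat, max_lat = max_lat,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, cell %g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  lon [%g, %g], lat [%g, %g]\n",
              x$min_lon, x$max_lon, x$min_lat, x$max_lat))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with vectors `lon` (length `n_cols`) and `lat` (length
#'   `n_rows`, northernmost first), plus matrices `lon_mat`/`lat_mat` of
#'   shape (`n_rows`, `n_cols`).
#' @export
cell_centres <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lon <- grid$min_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  lat <- grid$max_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  list(lon = lon, lat = lat,
       lon_mat = matrix(lon, grid$n_rows, grid$n_cols, byrow = TRUE),
       lat_mat = matrix(lat, grid$n_rows, grid$n_cols))
}

#' Locate points on a grid
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Point coordinates (decimal degrees).
#' @return A two-column integer matrix (`row`, `col`); `NA` rows for points
#'   outside the grid extent.
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- floor((lon - grid$min_lon) / grid$cell_size) + 1L
  row <- floor((grid$max_lat - lat) / grid$cell_size) + 1L
  # points exactly on the east/south edge belong to the last cell
  col[lon == grid$max_lon] <- grid$n_cols
  row[lat == grid$min_lat] <- grid$n_rows
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b, tol = 1e-9) {
  inherits(a, "grid_spec") && inherits(b, "grid_spec") &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$min_lon - b$min_lon) < tol && abs(a$min_lat - b$min_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' A raster grid of values
#'
#' Thin container pairing a [grid_spec()] with a value matrix (row 1 north)
#' used for elevation surfaces and other gridded covariates.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of shape (`n_rows`, `n_cols`); `NA` marks
#'   no-data cells.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("values shape (%d, %d) does not match grid (%d, %d)",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  structure(list(grid = grid, values = values), class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("raster_grid: %d x %d, values in [%g, %g], %d NA cells\n",
              x$grid$n_rows, x$grid$n_cols, rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(lon < -180 | lon > 180))
    stop("longitude out of range [-180, 180]")
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]")
  invisible(TRUE)
}
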