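#' Define a regular longitude-latitude grid
#'
#' A grid is an origin (south-west corner), a cell size in degrees along each
#' axis, and a number of columns and rows. Cell `(i, j)` (0-based column `i`,
#' row `j`) occupies the half-open box
#' `[origin_lon + i * cell_size_lon, origin_lon + (i + 1) * cell_size_lon)` by
#' `[origin_lat + j * cell_size_lat, origin_lat + (j + 1) * cell_size_lat)`,
#' so adjoining cells never share area and a point falls in exactly one cell.
#' All geometry in the package is planar in degrees: the study domains are
#' equatorial, where the distortion of treating a degree box as a rectangle is
#' negligible at the 0.083-0.33 degree scales used.
#'
#' @param origin_lon,origin_lat South-west corner, decimal degrees.
#' @param cell_size_lon,cell_size_lat Cell sizes in degrees; must be positive.
#' @param n_cols,n_rows Grid dimensions; at least 1.
#'
#' @return A `grid_spec` object.
#' @export
#' @examples
#' fine <- grid_spec(30, -1, 0.0833, 0.0833, 48, 60)
#' coarse <- grid_spec(30, -1, 0.3, 0.3, 14, 17)
grid_spec <- function(origin_lon, origin_lat, cell_size_lon, cell_size_lat,
                      n_cols, n_rows) {
  stopifnot(
    is.numeric(origin_lon), is.numeric(origin_lat),
    cell_size_lon > 0, cell_size_lat > 0,
    n_cols >= 1, n_rows >= 1,
    n_cols == as.integer(n_cols), n_rows == as.integer(n_rows)
  )
  structure(
    list(
      origin_lon = as.numeric(origin_lon),
      origin_lat = as.numeric(origin_lat),
      cell_size_lon = as.numeric(cell_size_lon),
      cell_size_lat = as.numeric(cell_size_lat),
      n_cols = as.integer(n_cols),
      n_rows = as.integer(n_rows)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d cols x %d rows, cell %.6g x %.6g deg, origin (%.6g, %.6g)\n",
    x$n_cols, x$n_rows, x$cell_size_lon, x$cell_size_lat,
    x$origin_lon, x$origin_lat
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("grid %dx%d @ (%.6g,%.6g) step (%.6g,%.6g)",
          x$n_cols, x$n_rows, x$origin_lon, x$origin_lat,
          x$cell_size_lon, x$cell_size_lat)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

grids_identical <- function(a, b, tol = 1e-9) {
  is_grid_spec(a) && is_grid_spec(b) &&
    a$n_cols == b$n_cols && a$n_rows == b$n_rows &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size_lon - b$cell_size_lon) < tol &&
    abs(a$cell_size_lat - b$cell_size_lat) < tol
}

#' Cell geometry helpers
#'
#' `cell_bounds()` returns the half-open footprint of one cell;
#' `cell_centres()` the centre coordinates of every cell as a tibble;
#' `grid_extent()` the bounding box of the whole grid.
#'
#' @param grid A [grid_spec()].
#' @param col,row 0-based cell indices.
#' @return `cell_bounds()`: named numeric vector `lon_min/lon_max/lat_min/lat_max`;
#'   `cell_centres()`: tibble with columns `col`, `row`, `lon`, `lat`;
#'   `grid_extent()`: named numeric vector like `cell_bounds()`.
#' @export
cell_bounds <- function(grid, col, row) {
  stopifnot(is_grid_spec(grid), col >= 0, col < grid$n_cols,
            row >= 0, row < grid$n_rows)
  c(
    lon_min = grid$origin_lon + col * grid$cell_size_lon,
    lon_max = grid$origin_lon + (col + 1) * grid$cell_size_lon,
    lat_min = grid$origin_lat + row * grid$cell_size_lat,
    lat_max = grid$origin_lat + (row + 1) * grid$cell_size_lat
  )
}

#' @rdname cell_bounds
#' @export
cell_centres <- function(grid) {
  stopifnot(is_grid_spec(grid))
  tidyr::expand_grid(
    row = seq_len(grid$n_rows) - 1L,
    col = seq_len(grid$n_cols) - 1L
  ) |>
    dplyr::mutate(
      lon = grid$origin_lon + (.data$col + 0.5) * grid$cell_size_lon,
      lat = grid$origin_lat + (.data$row + 0.5) * grid$cell_size_lat
    ) |>
    dplyr::select("col", "row", "lon", "lat")
}

#' @rdname cell_bounds
#' @export
grid_extent <- function(grid) {
  stopifnot(is_grid_spec(grid))
  c(
    lon_min = grid$origin_lon,
    lon_max = grid$origin_lon + grid$n_cols * grid$cell_size_lon,
    lat_min = grid$origin_lat,
    lat_max = grid$origin_lat + grid$n_rows * grid$cell_size_lat
  )
}

# 0-based column index of the cell whose half-open footprint contains lon,
# or NA outside the grid. Vectorised.
lon_to_col <- function(grid, lon) {
  i <- floor((lon - grid$origin_lon) / grid$cell_size_lon)
  i[i < 0 | i >= grid$n_cols] <- NA_real_
  as.integer(i)
}

lat_to_row <- function(grid, lat) {
  j <- floor((lat - grid$origin_lat) / grid$cell_size_lat)
  j[j < 0 | j >= grid$n_rows] <- NA_real_
  as.integer(j)
}
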