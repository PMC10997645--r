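#' Assign grid cells to named sub-region polygons by majority overlap
#'
#' Every cell is assigned to the polygon with the greatest overlap area with
#' the cell's half-open footprint; cells overlapping no polygon stay
#' unassigned. This generalises the usual majority-area rule for rasterising
#' administrative layers (the same rule the flood-district layer uses) to any
#' polygon set. Overlap areas are planar shoelace areas in square degrees.
#' Ties (equal overlap) go to the polygon listed first, so the result is
#' deterministic in the input order.
#'
#' @param grid A [grid_spec()].
#' @param polygons Named list of polygons; each polygon is a list of rings
#'   (2-column lon/lat matrices; first ring outer, later rings holes). Names
#'   must be unique.
#' @return A `region_map`: list with `grid`, `polygons`, and `assignment`
#'   (character matrix `n_rows x n_cols`, `NA` = unassigned).
#' @export
#' @examples
#' g <- grid_spec(0, 0, 1, 1, 4, 4)
#' polys <- list(A = list(rect_polygon(0, 2, 0, 4)),
#'               B = list(rect_polygon(2, 4, 0, 4)))
#' rm <- assign_cells(g, polys)
#' table(rm$assignment)
assign_cells <- function(grid, polygons) {
  stopifnot(is_grid_spec(grid))
  if (length(polygons) == 0) stop("empty polygon set")
  if (is.null(names(polygons)) || any(names(polygons) == "") ||
      anyDuplicated(names(polygons))) {
    stop("polygons must have unique non-empty names")
  }
  for (nm in names(polygons)) {
    if (polygon_area(polygons[[nm]]) <= 0) {
      stop("degenerate (zero-area) polygon: ", nm)
    }
  }
  best_area <- matrix(0, grid$n_rows, grid$n_cols)
  assignment <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  for (nm in names(polygons)) {
    rings <- polygons[[nm]]
    bb <- ring_bbox(rings[[1]])
    i0 <- max(0L, floor((bb["xmin"] - grid$origin_lon) / grid$cell_size_lon))
    i1 <- min(grid$n_cols - 1L,
              ceiling((bb["xmax"] - grid$origin_lon) / grid$cell_size_lon))
    j0 <- max(0L, floor((bb["ymin"] - grid$origin_lat) / grid$cell_size_lat))
    j1 <- min(grid$n_rows - 1L,
              ceiling((bb["ymax"] - grid$origin_lat) / grid$cell_size_lat))
    if (i1 < i0 || j1 < j0) next
    for (j in j0:j1) {
      y0 <- grid$origin_lat + j * grid$cell_size_lat
      y1 <- y0 + grid$cell_size_lat
      for (i in i0:i1) {
        x0 <- grid$origin_lon + i * grid$cell_size_lon
        x1 <- x0 + grid$cell_size_lon
        a <- polygon_box_overlap(rings, x0, x1, y0, y1)
        if (a > best_area[j + 1, i + 1]) {
          best_area[j + 1, i + 1] <- a
          assignment[j + 1, i + 1] <- nm
        }
      }
    }
  }
  structure(
    list(grid = grid, polygons = polygons, assignment = assignment),
    class = "region_map"
  )
}

is_region_map <- function(x) inherits(x, "region_map")

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %s, %d sub-regions, %d unassigned cells\n",
              format(x$grid), length(x$polygons), sum(is.na(x$assignment))))
  invisible(x)
}

#' Tidy a region map into a per-cell tibble
#'
#' @param x A region map from [assign_cells()].
#' @param ... Unused.
#' @return Tibble with columns `col`, `row`, `lon`, `lat`, `sub_region`.
#' @method tidy region_map
#' @export
tidy.region_map <- function(x, ...) {
  cc <- cell_centres(x$grid)
  cc$sub_region <- x$assignment[cbind(cc$row + 1L, cc$col + 1L)]
  cc
}

#' Per-region cell counts
#'
#' @param regions A region map.
#' @return Tibble with columns `sub_region`, `n_cells`.
#' @export
region_cell_counts <- function(regions) {
  stopifnot(is_region_map(regions))
  tidy.region_map(regions) |>
    dplyr::filter(!is.na(.data$sub_region)) |>
    dplyr::count(.data$sub_region, name = "n_cells")
}

#' Axis-aligned rectangle polygon
#'
#' Convenience constructor for a single counter-clockwise rectangular ring.
#'
#' @param lon_min,lon_max,lat_min,lat_max Rectangle bounds, degrees.
#' @return A 4x2 lon/lat matrix usable as a polygon ring.
#' @export
rect_polygon <- function(lon_min, lon_max, lat_min, lat_max) {
  stopifnot(lon_max > lon_min, lat_max > lat_min)
  rect_ring(lon_min, lon_max, lat_min, lat_max)
}
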