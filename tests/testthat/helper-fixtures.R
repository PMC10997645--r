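# Shared fixtures and independent brute-force oracles. The oracles stay
# deliberately naive (explicit loops over cells/vertices) so they cannot
# share a defect with the vectorised implementation paths.

unit_grid <- function(n_cols, n_rows, cell = 1, origin = c(0, 0)) {
  grid_spec(origin[1], origin[2], cell, cell, n_cols, n_rows)
}

# Brute-force overlap area between one rectangle polygon and one cell,
# by dense midpoint sampling (only used at coarse tolerance).
sample_overlap_area <- function(rings, xmin, xmax, ymin, ymax, n = 200) {
  xs <- seq(xmin, xmax, length.out = n + 1); xs <- (xs[-1] + xs[-(n + 1)]) / 2
  ys <- seq(ymin, ymax, length.out = n + 1); ys <- (ys[-1] + ys[-(n + 1)]) / 2
  ring <- rings[[1]]
  inside <- function(px, py) {
    # ray casting
    n_v <- nrow(ring); cross <- 0
    for (k in seq_len(n_v)) {
      x1 <- ring[k, 1]; y1 <- ring[k, 2]
      k2 <- if (k == n_v) 1 else k + 1
      x2 <- ring[k2, 1]; y2 <- ring[k2, 2]
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) cross <- cross + 1
      }
    }
    cross %% 2 == 1
  }
  hits <- 0
  for (px in xs) for (py in ys) if (inside(px, py)) hits <- hits + 1
  hits / (n * n) * (xmax - xmin) * (ymax - ymin)
}

# Brute-force zonal statistic: explicit loop over every cell.
brute_zonal <- function(field, regions, stat, mask = NULL) {
  g <- field$grid
  acc <- list()
  for (j in seq_len(g$n_rows)) for (i in seq_len(g$n_cols)) {
    r <- regions$assignment[j, i]
    v <- field$values[j, i]
    if (is.na(r) || is.na(v)) next
    if (!is.null(mask)) {
      mv <- if (is_rf(mask)) mask$values[j, i] else mask[j, i]
      if (is.na(mv) || mv == 0) next
    }
    acc[[r]] <- c(acc[[r]], v)
  }
  fn <- switch(stat, mean = mean, sum = sum, min = min, max = max)
  vapply(acc, fn, 0)
}

is_rf <- function(x) inherits(x, "raster_field")

# Daily cube with reproducible random increments.
random_daily_cube <- function(grid, year = 2015, seed = 1, max_inc = 0.3) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  set.seed(seed)
  vals <- array(stats::runif(length(dates) * grid$n_rows * grid$n_cols,
                             0, max_inc),
                c(length(dates), grid$n_rows, grid$n_cols))
  flux_cube(grid, dates, vals, mode = "daily")
}

# Two-sub-region fixture on a tiny grid: left half A, right half B.
two_region_fixture <- function(n = 4) {
  g <- unit_grid(n, n)
  polys <- list(A = list(rect_polygon(0, n / 2, 0, n)),
                B = list(rect_polygon(n / 2, n, 0, n)))
  list(grid = g, polygons = polys, regions = assign_cells(g, polys))
}
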