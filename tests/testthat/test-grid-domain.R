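test_that("grid cells are half-open boxes with 0-based indexing", {
  g <- grid_spec(30, -1, 0.5, 0.5, 4, 4)
  b <- cell_bounds(g, 0, 0)
  expect_equal(unname(b), c(30, 30.5, -1, -0.5))
  # a point on the shared edge belongs to the upper cell only
  expect_identical(lon_to_col(g, 30.5), 1L)
  expect_identical(lat_to_row(g, -0.5), 1L)
  expect_true(is.na(lon_to_col(g, 32.0)))  # right edge is exclusive
  expect_error(grid_spec(0, 0, 0, 1, 2, 2))
})

test_that("cells fully inside one polygon are all assigned to it", {
  g <- unit_grid(2, 2)
  rm <- assign_cells(g, list(only = list(rect_polygon(-1, 3, -1, 3))))
  expect_true(all(rm$assignment == "only"))
})

test_that("a cell straddling two polygons goes to the majority polygon", {
  g <- unit_grid(1, 1)
  polys <- list(big = list(rect_polygon(0, 0.7, 0, 1)),
                small = list(rect_polygon(0.7, 1, 0, 1)))
  rm <- assign_cells(g, polys)
  expect_identical(rm$assignment[1, 1], "big")
})

test_that("midline split of a 4x4 grid assigns 8 cells per side, matching brute force", {
  fx <- two_region_fixture(4)
  expect_identical(as.integer(table(fx$regions$assignment)), c(8L, 8L))
  # brute-force check of per-cell overlap areas for every cell
  for (j in 0:3) for (i in 0:3) {
    b <- cell_bounds(fx$grid, i, j)
    areas <- vapply(fx$polygons, function(p) {
      sample_overlap_area(p, b["lon_min"], b["lon_max"],
                          b["lat_min"], b["lat_max"], n = 40)
    }, 0)
    expect_identical(fx$regions$assignment[j + 1, i + 1],
                     names(which.max(areas)))
  }
})

test_that("assign_cells rejects empty and degenerate polygon sets", {
  g <- unit_grid(2, 2)
  expect_error(assign_cells(g, list()), "empty")
  degen <- list(flat = list(matrix(c(0, 0, 1, 0, 2, 0), ncol = 2, byrow = TRUE)))
  expect_error(assign_cells(g, degen), "flat")
})

test_that("assign_cells is idempotent and area-consistent", {
  g <- unit_grid(5, 3)
  polys <- list(A = list(rect_polygon(0, 2.3, 0, 3)),
                B = list(rect_polygon(2.3, 5, 0, 1.6)))
  r1 <- assign_cells(g, polys)
  r2 <- assign_cells(g, polys)
  expect_identical(r1$assignment, r2$assignment)
  expect_lte(sum(region_cell_counts(r1)$n_cells), g$n_cols * g$n_rows)
})

test_that("regrid leaves a field unchanged on an identical grid", {
  g <- unit_grid(3, 3)
  set.seed(11)
  f <- raster_field(g, matrix(rnorm(9), 3, 3))
  for (m in c("area_weighted_mean", "sum_conserving", "nearest")) {
    expect_equal(regrid(f, g, m)$values, f$values, tolerance = 1e-12)
  }
})

test_that("area-weighted mean of equal-area cells is the plain mean", {
  src <- raster_field(unit_grid(2, 2), matrix(1:4, 2, 2))
  out <- regrid(src, grid_spec(0, 0, 2, 2, 1, 1), "area_weighted_mean")
  expect_equal(out$values[1, 1], 2.5)
})

test_that("sum-conserving regrid conserves tonnes, including nested random grids", {
  src <- raster_field(unit_grid(2, 2), matrix(c(10, 0, 0, 10), 2, 2),
                      units = "t")
  out <- regrid(src, grid_spec(0, 0, 2, 2, 1, 1), "sum_conserving")
  expect_equal(out$values[1, 1], 20)
  set.seed(7)
  for (rep in 1:20) {
    nc <- sample(2:6, 1); nr <- sample(2:6, 1)
    src <- raster_field(unit_grid(nc, nr),
                        matrix(runif(nc * nr, 0, 100), nr, nc), units = "t")
    # finer target covering the same extent
    k <- sample(2:4, 1)
    tgt <- grid_spec(0, 0, 1 / k, 1 / k, nc * k, nr * k)
    out <- regrid(src, tgt, "sum_conserving")
    expect_equal(sum(out$values), sum(src$values), tolerance = 1e-9)
  }
})

test_that("nearest regrid samples the source cell containing the target centre", {
  src <- raster_field(unit_grid(2, 2), matrix(c(1, 2, 3, 4), 2, 2))
  tgt <- grid_spec(0, 0, 0.5, 0.5, 4, 4)
  out <- regrid(src, tgt, "nearest")
  # target cell centred at (0.25, 0.25) lies in source cell (0,0)
  expect_equal(out$values[1, 1], src$values[1, 1])
  expect_equal(out$values[4, 4], src$values[2, 2])
})

test_that("regrid validates grids and method/kind compatibility", {
  f <- raster_field(unit_grid(2, 2), matrix(1, 2, 2))
  far <- grid_spec(100, 100, 1, 1, 2, 2)
  expect_error(regrid(f, far, "nearest"), "disjoint")
  expect_error(regrid(f, unit_grid(1, 1, cell = 2), "majority"),
               "categorical")
  cat_f <- raster_field(unit_grid(2, 2),
                        matrix(c("a", "a", "b", "b"), 2, 2),
                        kind = "categorical", levels = c("a", "b"))
  expect_error(regrid(cat_f, unit_grid(1, 1, cell = 2), "sum_conserving"))
  maj <- regrid(cat_f, grid_spec(0, 0, 2, 2, 1, 1), "majority")
  expect_true(maj$values[1, 1] %in% c("a", "b"))
})

test_that("zonal statistics match explicit loops, with and without mask", {
  fx <- two_region_fixture(4)
  g <- fx$grid
  set.seed(21)
  vals <- matrix(runif(16, 0, 50), 4, 4)
  vals[2, 3] <- NA  # a missing cell must be skipped, not zeroed
  f <- raster_field(g, vals)
  prod <- matrix(rbinom(16, 1, 0.5), 4, 4)
  for (st in c("mean", "sum", "min", "max")) {
    got <- zonal_stat(f, fx$regions, st)
    want <- brute_zonal(f, fx$regions, st)
    expect_equal(stats::setNames(got$value, got$sub_region), want[got$sub_region])
    gotm <- zonal_stat(f, fx$regions, st, mask = prod)
    wantm <- brute_zonal(f, fx$regions, st, mask = prod)
    expect_equal(stats::setNames(gotm$value, gotm$sub_region),
                 wantm[gotm$sub_region])
  }
})

test_that("simple zonal cases: mean of two cells, sum skips missing", {
  g <- unit_grid(3, 1)
  rm <- assign_cells(g, list(A = list(rect_polygon(0, 3, 0, 1))))
  f <- raster_field(g, matrix(c(10, 20, NA), 1, 3))
  expect_equal(zonal_stat(f, rm, "mean")$value, 15)
  expect_equal(zonal_stat(f, rm, "sum")$value, 30)
  expect_equal(zonal_stat(f, rm, "sum")$n_cells, 2L)
})

test_that("a region with no contributing cells is missing, never zero", {
  g <- unit_grid(2, 1)
  polys <- list(A = list(rect_polygon(0, 2, 0, 1)),
                B = list(rect_polygon(5, 6, 5, 6)))  # off-grid
  rm <- assign_cells(g, polys)
  z <- zonal_stat(raster_field(g, matrix(1, 1, 2)), rm, "sum")
  expect_true(is.na(z$value[z$sub_region == "B"]))
  expect_error(zonal_stat(raster_field(unit_grid(3, 3), matrix(1, 3, 3)),
                          rm, "sum"), "grid")
})

test_that("zonal sum over a fully assigned grid recovers the global sum", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    fx <- two_region_fixture(n)
    f <- raster_field(fx$grid, matrix(runif(n * n), n, n))
    z <- zonal_stat(f, fx$regions, "sum")
    expect_equal(sum(z$value), sum(f$values), tolerance = 1e-12)
  }
})

test_that("region polygons round-trip through GeoJSON", {
  polys <- list(A = list(rect_polygon(0, 1.5, 0, 2)),
                B = list(rect_polygon(1.5, 3, 0, 2)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson_polygons(polys, path, properties = list(A = list(level = 2)))
  back <- read_geojson_polygons(path)
  expect_identical(names(back$polygons), c("A", "B"))
  expect_equal(back$polygons$A[[1]], polys$A[[1]])
  expect_equal(back$properties$A$level, 2)
})
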