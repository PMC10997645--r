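lookup_ab <- data.frame(sub_region = c("A", "B"), region = c("RA", "RB"))

test_that("unit conversion factors leave a raster unchanged", {
  fx <- two_region_fixture(4)
  pr <- production_raster(fx$grid, matrix(runif(16, 0, 100), 4, 4),
                          year = 2017, season = "annual")
  out <- apply_conversion(pr, data.frame(region = c("RA", "RB"),
                                         factor = c(1, 1)),
                          fx$regions, lookup_ab, target_year = 2015)
  expect_equal(out$values, pr$values)
  expect_identical(attr(out, "year"), 2015)
})

test_that("a single-region factor scales every cell", {
  g <- unit_grid(2, 1)
  rm <- assign_cells(g, list(A = list(rect_polygon(0, 2, 0, 1))))
  pr <- production_raster(g, matrix(c(10, 20), 1, 2), year = 2017)
  out <- apply_conversion(pr, data.frame(region = "RA", factor = 0.5), rm,
                          data.frame(sub_region = "A", region = "RA"), 2015)
  expect_equal(out$values, matrix(c(5, 10), 1, 2))
})

test_that("two-region conversion equals an explicit per-cell multiply", {
  fx <- two_region_fixture(4)
  set.seed(14)
  vals <- matrix(runif(16, 0, 500), 4, 4)
  pr <- production_raster(fx$grid, vals, year = 2017)
  factors <- data.frame(region = c("RA", "RB"), factor = c(1.2, 0.8))
  out <- apply_conversion(pr, factors, fx$regions, lookup_ab, 2015)
  for (j in 1:4) for (i in 1:4) {
    f <- if (fx$regions$assignment[j, i] == "A") 1.2 else 0.8
    expect_equal(out$values[j, i], vals[j, i] * f)
  }
})

test_that("a missing factor is reported by region name", {
  fx <- two_region_fixture(2)
  pr <- production_raster(fx$grid, matrix(1, 2, 2), year = 2017)
  expect_error(
    apply_conversion(pr, data.frame(region = "RA", factor = 1),
                     fx$regions, lookup_ab, 2015),
    "RB"
  )
})

test_that("survey-derived factors interpolate regional change linearly in time", {
  # unchanged production -> factor exactly 1 regardless of years
  f <- derive_conversion_factors(
    data.frame(region = "N", tonnes = 120),
    data.frame(region = "N", tonnes = 120),
    early_year = 2009, late_year = 2018, target_year = 2015, base_year = 2017
  )
  expect_equal(f$factor, 1)
  # doubling between anchors: closed-form interpolation oracle
  f2 <- derive_conversion_factors(
    data.frame(region = "N", tonnes = 100),
    data.frame(region = "N", tonnes = 200),
    early_year = 2010, late_year = 2020, target_year = 2015, base_year = 2017
  )
  interp <- function(y) 100 + (200 - 100) * (y - 2010) / (2020 - 2010)
  expect_equal(f2$factor, interp(2015) / interp(2017))
  expect_equal(interp(2015), 150)
  expect_error(derive_conversion_factors(
    data.frame(region = "N", tonnes = 0),
    data.frame(region = "N", tonnes = 10),
    2010, 2020, 2015, 2017), "zero")
  expect_error(derive_conversion_factors(
    data.frame(region = "N", tonnes = -5),
    data.frame(region = "N", tonnes = 10),
    2010, 2020, 2015, 2017), "non-negative")
})

test_that("seasonal splitting honours the national default and printed overrides", {
  g <- unit_grid(3, 1)
  polys <- list(Default = list(rect_polygon(0, 1, 0, 1)),
                WestNile = list(rect_polygon(1, 2, 0, 1)),
                Lango = list(rect_polygon(2, 3, 0, 1)))
  rm <- assign_cells(g, polys)
  splits <- seasonal_split_table(
    names(polys),
    overrides = data.frame(
      sub_region = c("WestNile", "Lango"),
      share_season1 = c(0.30, 0.69),
      share_season2 = c(0.70, 0.31)
    )
  )
  pr <- production_raster(g, matrix(c(100, 100, 200), 1, 3), year = 2015)
  out <- split_seasons(pr, splits, rm)
  expect_equal(out$season1$values[1, ], c(60, 30, 138))
  expect_equal(out$season2$values[1, ], c(40, 70, 62))
  expect_identical(attr(out$season1, "season"), "season1")
})

test_that("splitting conserves tonnes cell by cell and rejects bad shares", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    fx <- two_region_fixture(n)
    share <- runif(1)
    splits <- seasonal_split_table(
      c("A", "B"),
      overrides = data.frame(sub_region = "B", share_season1 = share,
                             share_season2 = 1 - share)
    )
    pr <- production_raster(fx$grid, matrix(runif(n * n, 0, 1e4), n, n),
                            year = 2015)
    out <- split_seasons(pr, splits, fx$regions)
    expect_equal(out$season1$values + out$season2$values, pr$values,
                 tolerance = 1e-12)
    expect_equal(sum(out$season1$values) + sum(out$season2$values),
                 sum(pr$values), tolerance = 1e-9)
  }
  expect_error(
    seasonal_split_table("A", overrides = data.frame(
      sub_region = "A", share_season1 = 0.7, share_season2 = 0.4)),
    "sum to 1"
  )
})

test_that("unimodal sub-regions route all production to their single window", {
  fx <- two_region_fixture(2)
  splits <- seasonal_split_table(c("A", "B"), unimodal = "B")
  pr <- production_raster(fx$grid, matrix(100, 2, 2), year = 2015)
  out <- split_seasons(pr, splits, fx$regions)
  b_cells <- fx$regions$assignment == "B"
  expect_true(all(out$season1$values[b_cells] == 100))
  expect_true(all(out$season2$values[b_cells] == 0))
})

test_that("an already-split raster cannot be split again", {
  fx <- two_region_fixture(2)
  splits <- seasonal_split_table(c("A", "B"))
  pr <- production_raster(fx$grid, matrix(10, 2, 2), year = 2015)
  once <- split_seasons(pr, splits, fx$regions)
  expect_error(split_seasons(once$season1, splits, fx$regions),
               "already seasonal")
})
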