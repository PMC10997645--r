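test_that("the dose generator is deterministic per seed and seed-sensitive", {
  sc1 <- synthetic_scenario(seed = 11)
  sc1b <- synthetic_scenario(seed = 11)
  sc2 <- synthetic_scenario(seed = 12)
  c1 <- gen_flux_cube(sc1)
  expect_identical(c1$values, gen_flux_cube(sc1b)$values)
  expect_false(identical(c1$values, gen_flux_cube(sc2)$values))
})

test_that("noise-free, gradient-free scenarios give a constant dose cube", {
  sc <- synthetic_scenario(seed = 1, gradient = 0, seasonal_amplitude = 0,
                           noise_sd = 0)
  cube <- gen_flux_cube(sc)
  expect_true(all(abs(cube$values - sc$baseline_pod) < 1e-12))
})

test_that("a positive gradient accumulates more dose at the north-west corner", {
  sc <- synthetic_scenario(seed = 2, gradient = 0.08, noise_sd = 0)
  pod <- accumulate_pod(gen_flux_cube(sc), season_presets()$season1, 2015)
  g <- pod$grid
  nw <- pod$values[g$n_rows, 1]     # top-left cell
  se <- pod$values[1, g$n_cols]     # bottom-right cell
  expect_gt(nw, se)
})

test_that("occupancy bounds: zero gives an empty raster, one with no dispersion a constant", {
  sc0 <- synthetic_scenario(seed = 3, occupancy = 0)
  expect_true(all(gen_production(sc0)$raster$values == 0))
  sc1 <- synthetic_scenario(seed = 3, production_mode = "constant",
                            mean_tonnes = 42)
  expect_true(all(gen_production(sc1)$raster$values == 42))
  expect_error(synthetic_scenario(occupancy = 1.2))
})

test_that("survey base tables equal the regional sums of the generated raster", {
  sc <- synthetic_scenario(seed = 5)
  rg <- gen_regions(sc)
  out <- gen_production(sc, rg)
  # oracle: assign cells with the polygon machinery and sum per parent region
  regions <- assign_cells(sc$fine_grid, rg$polygons)
  lut <- stats::setNames(rg$lookup$region, rg$lookup$sub_region)
  z <- zonal_stat(out$raster, regions, "sum")
  want <- tapply(z$value, unname(lut[z$sub_region]), sum)
  got <- stats::setNames(out$survey_base$tonnes, out$survey_base$region)
  expect_equal(unname(got[names(want)]), as.numeric(want), tolerance = 1e-9)
  # survey anchors are the stated multiples of the base
  expect_equal(out$survey_early$tonnes,
               out$survey_base$tonnes * sc$survey_factor_early)
  expect_equal(out$survey_late$tonnes,
               out$survey_base$tonnes * sc$survey_factor_late)
})

test_that("generated regions partition the grid: every cell assigned, counts match blocks", {
  sc <- synthetic_scenario(seed = 6)
  rg <- gen_regions(sc)
  expect_length(rg$polygons, 14)
  regions <- assign_cells(sc$fine_grid, rg$polygons)
  expect_false(any(is.na(regions$assignment)))
  # oracle: centre membership in the rectangular layout
  blocks <- ozoneyield:::scenario_block_of_cells(sc)
  want <- table(blocks$sub_region)
  got <- region_cell_counts(regions)
  expect_equal(stats::setNames(got$n_cells, got$sub_region),
               stats::setNames(as.integer(want), names(want)))
  expect_identical(sum(rg$lookup$unimodal), 1L)
  expect_identical(dplyr::n_distinct(rg$lookup$region), 4L)
})

test_that("a single-region layout yields the whole-domain polygon", {
  sc <- synthetic_scenario(seed = 1, region_layout = c(1, 1),
                           n_parent_regions = 1, unimodal_sub_region = NULL)
  rg <- gen_regions(sc)
  expect_length(rg$polygons, 1)
  regions <- assign_cells(sc$fine_grid, rg$polygons)
  expect_true(all(regions$assignment == "SR01"))
})

test_that("stress layers respect their physical ranges", {
  sc <- synthetic_scenario(seed = 8)
  layers <- gen_stress_layers(sc)
  expect_true(all(layers$deprivation$values >= 0 &
                    layers$deprivation$values <= 100, na.rm = TRUE))
  expect_true(all(layers$spei$values >= -2.5 & layers$spei$values <= 2.5,
                  na.rm = TRUE))
  expect_true(all(layers$temperature$values >= 20 &
                    layers$temperature$values <= 38, na.rm = TRUE))
  expect_true(all(layers$flood$values >= 0, na.rm = TRUE))
  expect_true(all(layers$soil_nutrient$values %in% soil_constraint_classes()))
})

test_that("benign stress parameters floor the six-layer composite at exactly 6", {
  sc <- synthetic_scenario(seed = 9, benign_stress = TRUE)
  layers <- gen_stress_layers(sc)
  layers$ozone_yl <- raster_field(sc$fine_grid,
                                  matrix(0, sc$fine_grid$n_rows,
                                         sc$fine_grid$n_cols), units = "%")
  res <- score_stress_layers(layers)
  expect_true(all(res$composite$values == 6))
})

test_that("degenerate scenarios reproduce their closed-form truth end to end", {
  region_pod <- stats::setNames(seq(1, 20, length.out = 14),
                                sprintf("SR%02d", 1:14))
  sc <- synthetic_scenario(seed = 13, pod_mode = "per_region_constant",
                           production_mode = "constant",
                           region_pod = region_pod)
  rg <- gen_regions(sc)
  regions <- assign_cells(sc$fine_grid, rg$polygons)
  cube <- gen_flux_cube(sc)
  pods <- list(
    season1 = accumulate_pod(cube, season_presets()$season1, 2015),
    season2 = accumulate_pod(cube, season_presets()$season2, 2015),
    unimodal = accumulate_pod(cube, season_presets()$karamoja, 2015)
  )
  splits <- seasonal_split_table(rg$lookup$sub_region,
                                 unimodal = "SR14")
  seasonal <- split_seasons(gen_production(sc, rg)$raster, splits, regions)
  a <- run_assessment(pods, default_flux_effect_model(), seasonal, regions,
                      unimodal_windows = c(SR14 = "unimodal"))
  truth <- scenario_truth(sc, splits = splits)
  got <- a$table |>
    dplyr::filter(.data$season != "annual", .data$sub_region != "National") |>
    dplyr::arrange(.data$sub_region, .data$season)
  want <- dplyr::arrange(truth, .data$sub_region, .data$season)
  expect_equal(got$production_loss_t, want$production_loss_t,
               tolerance = 1e-9)
  expect_equal(got$mean_yield_loss_pct, want$mean_yield_loss_pct,
               tolerance = 1e-9)
  expect_identical(got$n_cells, want$n_cells)
})
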