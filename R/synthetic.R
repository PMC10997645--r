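#' Synthetic assessment scenario
#'
#' Bundles every knob of the synthetic input generators with a single seed.
#' The default scenario mirrors the scales of the Ugandan bean assessment:
#' a ~4 x 5 degree equatorial domain, a 0.3 degree exposure grid over a
#' 0.0833 degree production grid, 14 rectangular sub-regions grouped into 4
#' regions with one unimodal sub-region, a smooth north-west-high daily dose
#' field with a seasonal cycle, patchy log-normal production, and five
#' environmental stress layers.
#'
#' All randomness flows from `seed` through named substreams (one per
#' generator), so regenerating one input never perturbs the others and the
#' same scenario is byte-identical across runs.
#'
#' Two degenerate modes support exact oracles: `pod_mode =
#' "per_region_constant"` makes every cell of a sub-region accumulate
#' exactly its region's prescribed dose over any 90-day window, and
#' `production_mode = "constant"` puts the same tonnage in every cell; with
#' both set, [scenario_truth()] states the full loss table in closed form.
#'
#' @param seed Integer master seed.
#' @param year Simulated calendar year.
#' @param fine_grid,coarse_grid [grid_spec()]s for production and exposure.
#' @param region_layout `c(n_blocks_lon, n_blocks_lat)`; their product is
#'   the number of sub-regions.
#' @param n_parent_regions Number of parent regions the sub-regions are
#'   grouped into (round-robin blocks).
#' @param unimodal_sub_region Name of the sub-region with a single season
#'   (`NULL` for none).
#' @param pod_mode `"gradient"` (smooth field + seasonality + noise) or
#'   `"per_region_constant"`.
#' @param baseline_pod Mean daily dose increment, mmol m^-2 d^-1.
#' @param gradient Extra daily increment at the north-west corner (decaying
#'   to zero at the south-east corner), mmol m^-2 d^-1.
#' @param seasonal_amplitude Amplitude of the annual sinusoid, mmol m^-2 d^-1.
#' @param noise_sd Daily cell noise standard deviation, mmol m^-2 d^-1.
#' @param region_pod For `per_region_constant`: named 90-day dose per
#'   sub-region (mmol m^-2); unnamed scalar recycled.
#' @param production_mode `"lognormal"` or `"constant"`.
#' @param occupancy Probability a fine cell produces at all.
#' @param mean_tonnes Mean tonnes per producing cell.
#' @param dispersion Log-scale standard deviation of cell tonnes.
#' @param survey_factor_early,survey_factor_late Per-parent-region
#'   multipliers turning the generated base-year regional totals into the
#'   two synthetic survey snapshots (recycled if scalar).
#' @param survey_years,base_year,target_year Survey anchor years, the
#'   raster's base year and the assessment year.
#' @param benign_stress If `TRUE` every stress layer sits in its least-risk
#'   class everywhere (composite score floor).
#' @return A `synthetic_scenario` list.
#' @export
#' @examples
#' sc <- synthetic_scenario(seed = 7)
#' cube <- gen_flux_cube(sc)
synthetic_scenario <- function(
    seed = 1L,
    year = 2015L,
    fine_grid = grid_spec(30, -1, 0.0833, 0.0833, 48, 60),
    coarse_grid = grid_spec(30, -1, 0.3, 0.3, 14, 17),
    region_layout = c(2L, 7L),
    n_parent_regions = 4L,
    unimodal_sub_region = "SR14",
    pod_mode = c("gradient", "per_region_constant"),
    baseline_pod = 0.15,
    gradient = 0.08,
    seasonal_amplitude = 0.04,
    noise_sd = 0.02,
    region_pod = 12,
    production_mode = c("lognormal", "constant"),
    occupancy = 0.6,
    mean_tonnes = 350,
    dispersion = 1,
    survey_factor_early = c(0.70, 0.85, 1.10, 1.25),
    survey_factor_late = c(1.05, 0.95, 0.90, 1.10),
    survey_years = c(2009L, 2018L),
    base_year = 2017L,
    target_year = 2015L,
    benign_stress = FALSE) {
  pod_mode <- match.arg(pod_mode)
  production_mode <- match.arg(production_mode)
  stopifnot(seed == as.integer(seed), occupancy >= 0, occupancy <= 1,
            mean_tonnes >= 0, dispersion >= 0,
            region_layout[1] >= 1, region_layout[2] >= 1,
            n_parent_regions >= 1,
            survey_years[1] < survey_years[2])
  if (baseline_pod < 0) stop("baseline daily dose must be non-negative")
  n_sub <- region_layout[1] * region_layout[2]
  sub_names <- sprintf("SR%02d", seq_len(n_sub))
  if (!is.null(unimodal_sub_region) &&
      !unimodal_sub_region %in% sub_names) {
    stop("unimodal_sub_region must be one of ", paste(sub_names, collapse = ", "))
  }
  if (is.null(names(region_pod))) {
    region_pod <- stats::setNames(rep_len(region_pod, n_sub), sub_names)
  }
  structure(
    list(seed = as.integer(seed), year = as.integer(year),
         fine_grid = fine_grid, coarse_grid = coarse_grid,
         region_layout = as.integer(region_layout),
         n_parent_regions = as.integer(n_parent_regions),
         unimodal_sub_region = unimodal_sub_region,
         pod_mode = pod_mode, baseline_pod = baseline_pod,
         gradient = gradient, seasonal_amplitude = seasonal_amplitude,
         noise_sd = noise_sd, region_pod = region_pod,
         production_mode = production_mode, occupancy = occupancy,
         mean_tonnes = mean_tonnes, dispersion = dispersion,
         survey_factor_early = rep_len(survey_factor_early, n_parent_regions),
         survey_factor_late = rep_len(survey_factor_late, n_parent_regions),
         survey_years = as.integer(survey_years),
         base_year = as.integer(base_year),
         target_year = as.integer(target_year),
         benign_stress = benign_stress),
    class = "synthetic_scenario"
  )
}

# Named substreams: one deterministic seed per generator so adding a
# generator never shifts the draws of another.
substream_seed <- function(scenario, name) {
  streams <- c(flux = 1L, production = 2L, regions = 3L, soil = 4L,
               spei = 5L, flood = 6L, temperature = 7L, deprivation = 8L,
               survey = 9L)
  if (!name %in% names(streams)) stop("unknown substream: ", name)
  (abs(scenario$seed) %% 1000003L) * 1009L + streams[[name]]
}

# Sub-region of each fine cell by centre membership in the rectangular
# layout. For an axis-aligned partition the majority-overlap rule and the
# centre rule coincide (no cell can have its majority on the far side of the
# boundary from its centre), so this is the arithmetic oracle for
# assign_cells on generated regions.
scenario_block_of_cells <- function(scenario) {
  g <- scenario$fine_grid
  nx <- scenario$region_layout[1]; ny <- scenario$region_layout[2]
  cc <- cell_centres(g)
  ext <- grid_extent(g)
  bx <- pmin(nx - 1L, floor(nx * (cc$lon - ext["lon_min"]) /
                              (ext["lon_max"] - ext["lon_min"])))
  by <- pmin(ny - 1L, floor(ny * (cc$lat - ext["lat_min"]) /
                              (ext["lat_max"] - ext["lat_min"])))
  idx <- bx * ny + by + 1L
  cc$sub_region <- sprintf("SR%02d", idx)
  cc
}

#' Generate the synthetic region partition
#'
#' Rectangular partition of the fine-grid extent into the scenario's named
#' sub-regions, grouped round-robin-in-blocks into parent regions, with the
#' scenario's unimodal sub-region flagged.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `polygons` (named list of rectangle polygons),
#'   `lookup` (tibble `sub_region`, `region`, `unimodal`) and
#'   `unimodal_sub_region`.
#' @export
gen_regions <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  g <- scenario$fine_grid
  nx <- scenario$region_layout[1]; ny <- scenario$region_layout[2]
  ext <- grid_extent(g)
  xs <- seq(ext["lon_min"], ext["lon_max"], length.out = nx + 1)
  ys <- seq(ext["lat_min"], ext["lat_max"], length.out = ny + 1)
  polys <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      nm <- sprintf("SR%02d", (i - 1L) * ny + j)
      polys[[nm]] <- list(rect_polygon(xs[i], xs[i + 1], ys[j], ys[j + 1]))
    }
  }
  n_sub <- nx * ny
  parents <- paste0("R", rep(seq_len(scenario$n_parent_regions),
                             each = ceiling(n_sub / scenario$n_parent_regions),
                             length.out = n_sub))
  lookup <- tibble::tibble(
    sub_region = sprintf("SR%02d", seq_len(n_sub)),
    region = parents,
    unimodal = sprintf("SR%02d", seq_len(n_sub)) %in%
      scenario$unimodal_sub_region
  )
  list(polygons = polys, lookup = lookup,
       unimodal_sub_region = scenario$unimodal_sub_region)
}

#' Generate the synthetic daily dose cube
#'
#' In `gradient` mode the daily increment of a cell is
#' `max(0, baseline + gradient * nw_proximity + seasonal sinusoid + noise)`
#' on the coarse exposure grid, reproducing a north-west-high field with
#' month-scale variation. In `per_region_constant` mode the cube sits on the
#' fine grid and every cell of a sub-region yields exactly
#' `region_pod[sub_region] / 90` each day, so any 90-day window accumulates
#' the prescribed regional dose exactly.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A daily-mode [flux_cube()] covering the scenario year.
#' @export
gen_flux_cube <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dates <- seq(as.Date(sprintf("%d-01-01", scenario$year)),
               as.Date(sprintf("%d-12-31", scenario$year)), by = "day")
  nd <- length(dates)
  if (scenario$pod_mode == "per_region_constant") {
    g <- scenario$fine_grid
    blocks <- scenario_block_of_cells(scenario)
    daily <- matrix(NA_real_, g$n_rows, g$n_cols)
    daily[cbind(blocks$row + 1L, blocks$col + 1L)] <-
      unname(scenario$region_pod[blocks$sub_region]) / 90
    vals <- array(rep(daily, each = nd), c(nd, g$n_rows, g$n_cols))
    return(flux_cube(g, dates, vals, mode = "daily"))
  }
  g <- scenario$coarse_grid
  cc <- cell_centres(g)
  ext <- grid_extent(g)
  w <- ext["lon_max"] - ext["lon_min"]; h <- ext["lat_max"] - ext["lat_min"]
  d_nw <- sqrt(((cc$lon - ext["lon_min"]) / w)^2 +
                 ((ext["lat_max"] - cc$lat) / h)^2) / sqrt(2)
  prox <- 1 - d_nw
  spatial <- matrix(NA_real_, g$n_rows, g$n_cols)
  spatial[cbind(cc$row + 1L, cc$col + 1L)] <-
    scenario$baseline_pod + scenario$gradient * prox
  doy <- julian_day(dates)
  seasonal <- scenario$seasonal_amplitude * sin(2 * pi * (doy - 60) / 365.25)
  set.seed(substream_seed(scenario, "flux"))
  noise <- if (scenario$noise_sd > 0) {
    array(stats::rnorm(nd * g$n_rows * g$n_cols, 0, scenario$noise_sd),
          c(nd, g$n_rows, g$n_cols))
  } else {
    array(0, c(nd, g$n_rows, g$n_cols))
  }
  vals <- noise
  for (t in seq_len(nd)) {
    vals[t, , ] <- pmax(vals[t, , ] + spatial + seasonal[t], 0)
  }
  flux_cube(g, dates, vals, mode = "daily")
}

#' Generate synthetic production and the survey snapshots
#'
#' Cell production on the fine grid is Bernoulli(occupancy) x
#' LogNormal(mean `mean_tonnes`, log-sd `dispersion`) tonnes (or constant
#' `mean_tonnes` in `constant` mode). The two survey tables are the
#' generated base-year parent-region totals multiplied by the scenario's
#' stated early/late factors, so [derive_conversion_factors()] has a known
#' truth: factor(region) = interp(target)/interp(base) of those anchors.
#'
#' @param scenario A [synthetic_scenario()].
#' @param regions Output of [gen_regions()] (defaults to regenerating it).
#' @return List with `raster` (annual [production_raster()], base year),
#'   `survey_base`, `survey_early`, `survey_late` (tibbles `region`,
#'   `tonnes`).
#' @export
gen_production <- function(scenario, regions = gen_regions(scenario)) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  g <- scenario$fine_grid
  n <- g$n_rows * g$n_cols
  set.seed(substream_seed(scenario, "production"))
  if (scenario$production_mode == "constant") {
    tonnes <- rep(scenario$mean_tonnes, n)
  } else {
    occupied <- stats::rbinom(n, 1, scenario$occupancy)
    sdl <- scenario$dispersion
    meanlog <- log(scenario$mean_tonnes) - sdl^2 / 2
    tonnes <- occupied * stats::rlnorm(n, meanlog, sdl)
  }
  vals <- matrix(tonnes, g$n_rows, g$n_cols)
  raster <- production_raster(g, vals, year = scenario$base_year,
                              season = "annual")
  blocks <- scenario_block_of_cells(scenario)
  blocks$tonnes <- vals[cbind(blocks$row + 1L, blocks$col + 1L)]
  lut <- stats::setNames(regions$lookup$region, regions$lookup$sub_region)
  base <- blocks |>
    dplyr::mutate(region = unname(lut[.data$sub_region])) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(tonnes = sum(.data$tonnes), .groups = "drop")
  fe <- stats::setNames(scenario$survey_factor_early,
                        paste0("R", seq_along(scenario$survey_factor_early)))
  fl <- stats::setNames(scenario$survey_factor_late,
                        paste0("R", seq_along(scenario$survey_factor_late)))
  list(
    raster = raster,
    survey_base = base,
    survey_early = dplyr::mutate(base,
                                 tonnes = .data$tonnes * unname(fe[.data$region])),
    survey_late = dplyr::mutate(base,
                                tonnes = .data$tonnes * unname(fl[.data$region]))
  )
}

#' Generate the synthetic environmental stress layers
#'
#' Five layers on (or rasterisable onto) the fine grid with seeded spatial
#' structure inside the stated physical bounds: a five-class categorical
#' soil-nutrient constraint layer; a continuous 6-month drought index in
#' [-2.5, 2.5] (north wetter); district flood-occurrence counts delivered
#' through the majority-area rasteriser; mean daily maximum temperature in
#' roughly 20-38 deg C (north hotter); and a 0-100 deprivation index. With
#' `benign_stress = TRUE` every layer sits in its least-risk class, so the
#' six-layer composite (with a zero ozone layer) is exactly 6 everywhere.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Named list of [raster_field()]s: `soil_nutrient`, `spei`,
#'   `flood`, `temperature`, `deprivation`; the flood districts and counts
#'   are attached as attributes `districts` and `flood_counts`.
#' @export
gen_stress_layers <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  g <- scenario$fine_grid
  cc <- cell_centres(g)
  ext <- grid_extent(g)
  lat_norm <- (cc$lat - ext["lat_min"]) / (ext["lat_max"] - ext["lat_min"])
  lon_norm <- (cc$lon - ext["lon_min"]) / (ext["lon_max"] - ext["lon_min"])
  as_mat <- function(v) {
    m <- matrix(NA_real_, g$n_rows, g$n_cols)
    m[cbind(cc$row + 1L, cc$col + 1L)] <- v
    m
  }
  classes <- soil_constraint_classes()

  if (scenario$benign_stress) {
    soil <- raster_field(g, matrix(classes[1], g$n_rows, g$n_cols),
                         kind = "categorical", levels = classes)
    spei <- raster_field(g, as_mat(rep(0.5, nrow(cc))), units = "index")
    temperature <- raster_field(g, as_mat(rep(25, nrow(cc))), units = "degC")
    deprivation <- raster_field(g, as_mat(rep(5, nrow(cc))), units = "index")
    districts <- gen_regions(scenario)$polygons
    counts <- stats::setNames(rep(0, length(districts)), names(districts))
  } else {
    set.seed(substream_seed(scenario, "soil"))
    idx <- 0.5 * lat_norm + 0.3 * lon_norm + stats::rnorm(nrow(cc), 0, 0.15)
    soil_cls <- classes[pmin(5L, pmax(1L, 1L + floor(5 * (1 - idx))))]
    msoil <- matrix(NA_character_, g$n_rows, g$n_cols)
    msoil[cbind(cc$row + 1L, cc$col + 1L)] <- soil_cls
    soil <- raster_field(g, msoil, kind = "categorical", levels = classes)

    set.seed(substream_seed(scenario, "spei"))
    spei_v <- pmax(-2.5, pmin(2.5, -1 + 2 * lat_norm +
                                stats::rnorm(nrow(cc), 0, 0.3)))
    spei <- raster_field(g, as_mat(spei_v), units = "index")

    set.seed(substream_seed(scenario, "temperature"))
    temp_v <- pmax(20, pmin(38, 22 + 12 * lat_norm +
                              stats::rnorm(nrow(cc), 0, 0.8)))
    temperature <- raster_field(g, as_mat(temp_v), units = "degC")

    set.seed(substream_seed(scenario, "deprivation"))
    dep_v <- pmax(0, pmin(100, 60 + 25 * (1 - lon_norm) +
                            stats::rnorm(nrow(cc), 0, 10)))
    deprivation <- raster_field(g, as_mat(dep_v), units = "index")

    # districts: a finer 4 x 5 rectangular partition with seeded counts
    set.seed(substream_seed(scenario, "flood"))
    xs <- seq(ext["lon_min"], ext["lon_max"], length.out = 5)
    ys <- seq(ext["lat_min"], ext["lat_max"], length.out = 6)
    districts <- list()
    for (i in 1:4) for (j in 1:5) {
      districts[[sprintf("D%02d", (i - 1) * 5 + j)]] <-
        list(rect_polygon(xs[i], xs[i + 1], ys[j], ys[j + 1]))
    }
    counts <- stats::setNames(stats::rpois(length(districts), 2),
                              names(districts))
  }
  flood <- flood_layer_from_districts(districts, counts, g)
  out <- list(soil_nutrient = soil, spei = spei, flood = flood,
              temperature = temperature, deprivation = deprivation)
  attr(out, "districts") <- districts
  attr(out, "flood_counts") <- counts
  out
}

#' Closed-form truth table for a degenerate scenario
#'
#' For a scenario with `pod_mode = "per_region_constant"` and
#' `production_mode = "constant"`, states the per-sub-region and national
#' loss table in closed form: every cell of sub-region `r` carries dose
#' `region_pod[r]` (over any 90-day window), yield loss
#' `min(slope * dose, 99.9)` percent, per-cell seasonal production
#' `mean_tonnes * share`, and loss `P * yl / (100 - yl)`. Cell counts come
#' from centre membership in the rectangular layout, which for an
#' axis-aligned partition equals the majority-overlap assignment.
#'
#' @param scenario A degenerate [synthetic_scenario()] (see above).
#' @param model A `flux_effect_model`.
#' @param splits A seasonal split table covering the sub-regions.
#' @return Tibble matching [run_assessment()]'s seasonal rows:
#'   `sub_region`, `season`, `mean_yield_loss_pct`, `production_t`,
#'   `production_loss_t`, `n_cells`.
#' @export
scenario_truth <- function(scenario, model = default_flux_effect_model(),
                           splits = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$pod_mode != "per_region_constant" ||
      scenario$production_mode != "constant") {
    stop("closed-form truth requires per_region_constant dose and constant production")
  }
  counts <- scenario_block_of_cells(scenario) |>
    dplyr::count(.data$sub_region, name = "n_cells")
  if (is.null(splits)) {
    splits <- seasonal_split_table(
      counts$sub_region,
      unimodal = scenario$unimodal_sub_region %||% character()
    )
  }
  tbl <- dplyr::left_join(counts, splits, by = "sub_region")
  purrr::map_dfr(c("season1", "season2"), function(s) {
    share <- if (s == "season1") tbl$share_season1 else tbl$share_season2
    yl <- pmin(model$slope *
                 pmax(unname(scenario$region_pod[tbl$sub_region]) -
                        model$reference_pod, 0), 99.9)
    prod <- scenario$mean_tonnes * share * tbl$n_cells
    loss <- prod * yl / (100 - yl)
    out <- tibble::tibble(
      sub_region = tbl$sub_region, season = s,
      mean_yield_loss_pct = yl, production_t = prod,
      production_loss_t = loss, n_cells = tbl$n_cells
    )
    if (s == "season2") {
      uni <- tbl$unimodal
      out$mean_yield_loss_pct[uni] <- NA_real_
      out$production_t[uni] <- 0
      out$production_loss_t[uni] <- NA_real_
      out$n_cells[uni] <- 0L
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
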