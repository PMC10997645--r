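#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, validates types
#' and cross-field constraints (seasonal shares summing to 1, positive
#' slope, known regrid method and missing policy) and resolves every
#' default, so the returned object records the complete effective
#' configuration. [run_all()] writes this resolved configuration alongside
#' its outputs as `resolved.yaml`, from which the run is reproducible.
#'
#' Recognised top-level keys (all optional):
#' \describe{
#'   \item{`seed`}{integer master seed (default 1);}
#'   \item{`year`}{assessment year (default 2015);}
#'   \item{`outdir`}{output directory (default `"ozoneyield-run"`);}
#'   \item{`model`}{list `slope` (default 1.175), `intercept` (100),
#'     `reference_pod` (0);}
#'   \item{`scenario`}{overrides passed to [synthetic_scenario()]
#'     (generator parameters only);}
#'   \item{`windows`}{named list of `start_day`/`end_day` overrides for
#'     `season1`, `season2`, `unimodal`;}
#'   \item{`default_share_season1`}{national season-1 share (0.6);}
#'   \item{`season_splits`}{list of `{sub_region, share_season1,
#'     share_season2}` overrides;}
#'   \item{`regrid_method`}{`nearest` (default) or `area_weighted_mean`;}
#'   \item{`missing_policy`}{`error` (default), `skip` or `scale`;}
#'   \item{`class_maps`}{stress-scoring overrides, per layer.}
#' }
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "year", "outdir", "model", "scenario", "windows",
             "default_share_season1", "season_splits", "regrid_method",
             "missing_policy", "class_maps")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    seed = raw$seed %||% 1L,
    year = raw$year %||% 2015L,
    outdir = raw$outdir %||% "ozoneyield-run",
    model = utils::modifyList(
      list(slope = 1.175, intercept = 100, reference_pod = 0),
      raw$model %||% list()
    ),
    scenario = raw$scenario %||% list(),
    windows = raw$windows %||% list(),
    default_share_season1 = raw$default_share_season1 %||% 0.6,
    season_splits = raw$season_splits %||% list(),
    regrid_method = raw$regrid_method %||% "nearest",
    missing_policy = raw$missing_policy %||% "error",
    class_maps = raw$class_maps %||% list()
  )
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    stop("config key 'seed': must be an integer")
  }
  if (!is.numeric(cfg$model$slope) || !is.finite(cfg$model$slope)) {
    stop("config key 'model.slope': must be a finite number")
  }
  if (cfg$model$reference_pod < 0) {
    stop("config key 'model.reference_pod': must be non-negative")
  }
  if (!cfg$regrid_method %in% c("nearest", "area_weighted_mean")) {
    stop("config key 'regrid_method': must be 'nearest' or 'area_weighted_mean'")
  }
  if (!cfg$missing_policy %in% c("error", "skip", "scale")) {
    stop("config key 'missing_policy': must be error, skip or scale")
  }
  if (cfg$default_share_season1 < 0 || cfg$default_share_season1 > 1) {
    stop("config key 'default_share_season1': must lie in [0, 1]")
  }
  for (ov in cfg$season_splits) {
    need <- c("sub_region", "share_season1", "share_season2")
    if (!all(need %in% names(ov))) {
      stop("config key 'season_splits': each entry needs ",
           paste(need, collapse = ", "))
    }
    if (abs(ov$share_season1 + ov$share_season2 - 1) > 1e-9) {
      stop("config key 'season_splits.", ov$sub_region,
           "': shares must sum to 1")
    }
  }
  sc_known <- setdiff(names(formals(synthetic_scenario)),
                      c("seed", "year"))
  sc_unknown <- setdiff(names(cfg$scenario), sc_known)
  if (length(sc_unknown) > 0) {
    stop("unknown config key(s) under 'scenario': ",
         paste(sc_unknown, collapse = ", "))
  }
  win <- season_presets()
  for (nm in names(cfg$windows)) {
    if (!nm %in% c("season1", "season2", "unimodal")) {
      stop("config key 'windows': unknown window ", nm)
    }
    w <- cfg$windows[[nm]]
    tgt <- if (nm == "unimodal") "karamoja" else nm
    win[[tgt]] <- season_window(tgt, w$start_day, w$end_day)
  }
  cfg$resolved_windows <- win
  structure(cfg, class = "run_config")
}

#' Run the complete synthetic assessment pipeline
#'
#' Executes, in order: input generation (regions, daily dose cube,
#' production and surveys, stress layers), seasonal dose accumulation,
#' regridding of the coarse dose fields onto the production grid,
#' survey-based year conversion, seasonal production splitting, the
#' dose-to-loss assessment, and stress scoring. All artifacts are written
#' under `config$outdir` as CSV/GeoJSON/YAML, together with the resolved
#' configuration and a manifest of (file, md5, producing step).
#'
#' @param config A `run_config` from [load_config()] (or a path to a YAML
#'   config).
#' @return Invisibly, a list with `status` (0 on success), `manifest`
#'   (tibble `file`, `md5`, `step`), `assessment` (the `ozone_assessment`),
#'   and `stress` (scores + composite).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(file = character(), step = character())
  emit <- function(path, step) {
    manifest <<- dplyr::bind_rows(manifest,
                                  tibble::tibble(file = path, step = step))
    path
  }
  step <- "simulate"
  res <- tryCatch({
    scenario <- do.call(synthetic_scenario,
                        c(list(seed = config$seed, year = config$year),
                          config$scenario))
    regions_def <- gen_regions(scenario)
    cube <- gen_flux_cube(scenario)
    prod_gen <- gen_production(scenario, regions_def)
    layers <- gen_stress_layers(scenario)
    write_geojson_polygons(regions_def$polygons,
                           emit(file.path(outdir, "regions.geojson"), step))
    write_cube_csv(cube, emit(file.path(outdir, "pod_daily.csv"), step))
    write_raster_csv(prod_gen$raster,
                     emit(file.path(outdir, "production_base.csv"), step))
    write_table_csv(prod_gen$survey_early,
                    emit(file.path(outdir, "survey_early.csv"), step),
                    "regional survey totals, tonnes (early anchor)")

    step <- "accumulate"
    win <- config$resolved_windows
    pods_coarse <- list(
      season1 = accumulate_pod(cube, win$season1, config$year,
                               missing = config$missing_policy),
      season2 = accumulate_pod(cube, win$season2, config$year,
                               missing = config$missing_policy),
      unimodal = accumulate_pod(cube, win$karamoja, config$year,
                                missing = config$missing_policy)
    )

    step <- "regrid"
    fine <- scenario$fine_grid
    pods <- purrr::map(pods_coarse, function(p) {
      if (grids_identical(p$grid, fine)) p
      else regrid(p, fine, config$regrid_method)
    })
    for (nm in names(pods)) {
      write_raster_csv(pods[[nm]],
                       emit(file.path(outdir, paste0("pod_", nm, ".csv")),
                            step))
    }

    step <- "production"
    regions <- assign_cells(fine, regions_def$polygons)
    factors <- derive_conversion_factors(
      prod_gen$survey_early, prod_gen$survey_late,
      early_year = scenario$survey_years[1],
      late_year = scenario$survey_years[2],
      target_year = scenario$target_year,
      base_year = scenario$base_year
    )
    prod_target <- apply_conversion(
      prod_gen$raster, factors, regions,
      region_lookup = regions_def$lookup, target_year = scenario$target_year
    )
    splits <- seasonal_split_table(
      regions_def$lookup$sub_region,
      unimodal = regions_def$lookup$sub_region[regions_def$lookup$unimodal],
      overrides = if (length(config$season_splits) > 0) {
        dplyr::bind_rows(lapply(config$season_splits, tibble::as_tibble))
      },
      default_share_season1 = config$default_share_season1
    )
    seasonal <- split_seasons(prod_target, splits, regions)
    write_table_csv(factors,
                    emit(file.path(outdir, "conversion_factors.csv"), step),
                    "survey-interpolated regional conversion factors")
    write_raster_csv(seasonal$season1,
                     emit(file.path(outdir, "production_season1.csv"), step))
    write_raster_csv(seasonal$season2,
                     emit(file.path(outdir, "production_season2.csv"), step))

    step <- "assess"
    model <- default_flux_effect_model(
      slope = config$model$slope, intercept = config$model$intercept,
      reference_pod = config$model$reference_pod
    )
    uni <- regions_def$lookup$sub_region[regions_def$lookup$unimodal]
    assessment <- run_assessment(
      pods, model, seasonal, regions,
      region_lookup = regions_def$lookup,
      unimodal_windows = stats::setNames(rep("unimodal", length(uni)), uni)
    )
    write_table_csv(assessment$table,
                    emit(file.path(outdir, "loss_table.csv"), step),
                    c("per-sub-region ozone yield and production losses",
                      "units: %, tonnes"))
    for (s in c("season1", "season2")) {
      write_raster_csv(assessment$rasters$yield_loss[[s]],
                       emit(file.path(outdir, paste0("yield_loss_", s, ".csv")),
                            step))
      write_raster_csv(assessment$rasters$production_loss[[s]],
                       emit(file.path(outdir,
                                      paste0("production_loss_", s, ".csv")),
                            step))
    }

    step <- "stress"
    layers$ozone_yl <- assessment$rasters$yield_loss$season1
    stress <- score_stress_layers(layers, config$class_maps)
    write_raster_csv(stress$composite,
                     emit(file.path(outdir, "stress_composite.csv"), step))

    step <- "finalise"
    resolved <- unclass(config)
    resolved$resolved_windows <- lapply(resolved$resolved_windows, unclass)
    yaml::write_yaml(resolved,
                     emit(file.path(outdir, "resolved.yaml"), step))
    list(assessment = assessment, stress = stress, scenario = scenario)
  }, error = function(e) {
    stop("pipeline step '", step, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$md5 <- unname(tools::md5sum(manifest$file))
  write_table_csv(manifest, file.path(outdir, "manifest.csv"))
  invisible(list(status = 0L, manifest = manifest,
                 assessment = res$assessment, stress = res$stress))
}
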