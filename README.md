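# ozoneyield

Gridded ozone crop-risk assessment in R: from accumulated phytotoxic ozone
dose to sub-regional production losses and a composite multi-stress map.

## The problem

Surface ozone taken up through stomata reduces yields of sensitive crops
such as common bean. Where ozone monitoring is sparse, national risk
estimates combine modelled stomatal ozone flux with gridded production data
and an experimentally derived flux–effect relationship. `ozoneyield`
implements that pipeline for a two-season (bimodal) cropping system with an
optional unimodal exception region — the setting of the Ugandan bean
case study — plus a composite score that co-locates
ozone with soil, drought, flood, temperature and deprivation stresses.

The chain, in the field's standard notation:

* **Dose.** POD₃IAM per cell and season: daily dose increments summed over
  a 90-day window (presets: days 91–180, 257–346, and 182–271 for the
  unimodal region). From hourly flux,
  increments are `Σ_hours max(f − 3, 0) · 3600 · 10⁻⁶` mmol m⁻² d⁻¹.
* **Yield loss.** `%YL = 1.175 · max(POD − POD_ref, 0)` with `POD_ref = 0`
  for beans, slope-only (zero exposure ⇔ zero effect), clamped to
  [0, 99.9]. The slope can be refit from (dose, relative-yield) points by
  variance-weighted least squares with a profiled power-law variance
  (σ ∝ PODᵟ) and heteroscedasticity-robust intervals.
* **Production loss.** With observed production `P` and relative yield
  `RY = 1 − %YL/100`: `loss = P/RY − P = P·%YL/(100 − %YL)` tonnes.
* **Accounting.** Base-year production is moved to the assessment year by
  survey-interpolated regional conversion factors and split 60:40 between
  seasons (per-sub-region overrides; the unimodal region routes everything
  to its own window). Losses aggregate to sub-region, region and national
  rows at the cell level.
* **Stress score.** Six layers each scored 1–5 and summed → composite in
  [6, 30].

Every input has a seeded synthetic emulator (`synthetic_scenario()` and the
`gen_*()` generators), so the whole pipeline runs and is tested offline.

## Worked example

```r
library(ozoneyield)
library(dplyr)

sc   <- synthetic_scenario(seed = 7)        # study-scale synthetic inputs
rg   <- gen_regions(sc)                     # 14 sub-regions, 4 regions
cube <- gen_flux_cube(sc)                   # daily dose increments, 0.3°

win  <- season_presets()
pods <- lapply(list(season1 = win$season1, season2 = win$season2,
                    unimodal = win$karamoja),
               function(w) accumulate_pod(cube, w, 2015)) |>
  lapply(regrid, target = sc$fine_grid, method = "nearest")

regions <- assign_cells(sc$fine_grid, rg$polygons)
prod    <- gen_production(sc, rg)
factors <- derive_conversion_factors(prod$survey_early, prod$survey_late,
                                     2009, 2018, target_year = 2015,
                                     base_year = 2017)
factors
#> # A tibble: 4 × 2
#>   region factor
#>   <chr>   <dbl>
#> 1 R1      0.923
#> 2 R2      0.976
#> 3 R3      1.05
#> 4 R4      1.03

prod15   <- apply_conversion(prod$raster, factors, regions, rg$lookup, 2015)
splits   <- seasonal_split_table(rg$lookup$sub_region, unimodal = "SR14")
seasonal <- split_seasons(prod15, splits, regions)

a <- run_assessment(pods, default_flux_effect_model(), seasonal, regions,
                    region_lookup = rg$lookup,
                    unimodal_windows = c(SR14 = "unimodal"))
tidy(a) |> filter(season == "season1") |> head(4)
#> # A tibble: 4 × 7
#>   sub_region region season  mean_yield_loss_pct production_t production_loss_t
#>   <chr>      <chr>  <chr>                 <dbl>        <dbl>             <dbl>
#> 1 National   <NA>   season1                23.3      371615.           112285.
#> 2 SR01       R1     season1                22.3       20034.             5709.
#> 3 SR02       R1     season1                23.0       20086.             6019.
#> 4 SR03       R1     season1                23.8       28177.             8755.
glance(a)
#> # A tibble: 1 × 5
#>   production_t production_loss_t mean_yield_loss_s1 mean_yield_loss_s2 slope
#>          <dbl>             <dbl>              <dbl>              <dbl> <dbl>
#> 1      588807.           155294.               23.3               16.5  1.18
```

Read: under this synthetic scenario, season-1 mean yield loss over cells
with production data is 23.3%, on ~589 kt of annual production the ozone
loss is ~155 kt, and sub-region SR01's season-1 loss is ~5.7 kt on ~20 kt
of seasonal production. `autoplot()` maps any raster
(`autoplot(a$rasters$yield_loss$season1)`), and `plot_loss_table(tidy(a))`
draws the seasonal bar chart.

The published per-sub-region loss table ships as a reference dataset:

```r
uganda_bean_losses() |> aggregate_losses() |> filter(sub_region == "National")
#> # A tibble: 3 × 7  (season1 114356, season2 70137, annual 184493 t)
```

A single YAML file drives the whole pipeline (`run_all("run.yaml")`),
writing rasters, tables, a resolved-configuration snapshot and an md5
manifest.

## Package layout

* `R/grid-spec.R`, `R/geometry.R`, `R/region-map.R`, `R/regrid.R`,
  `R/zonal.R` — planar-degree grids, polygon overlap, majority assignment,
  conservative regridding, zonal statistics
* `R/flux-cube.R`, `R/exposure.R` — dose cubes, season windows, POD
  accumulation
* `R/dose-response.R` — flux–effect fit and application
* `R/production.R`, `R/loss-pipeline.R` — conversion factors, seasonal
  splits, loss accounting and aggregation
* `R/stress.R` — 1–5 stress scoring and the composite
* `R/synthetic.R` — seeded generators and closed-form truth
* `R/io.R`, `R/config.R` — CSV/GeoJSON/YAML readers and the `run_all()`
  driver
* `vignettes/ozone-crop-risk-methods.Rmd` — the methods account: model
  assumptions, defaults and their rationale, numerical choices,
  limitations
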