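#' Crop-stress layers and their default 1-5 scoring
#'
#' A stress layer is a [raster_field()] (continuous or categorical) with a
#' layer name; [score_layer()] turns it into integer scores 1 (very low risk
#' to crop yield) to 5 (very high risk). Continuous layers are binned by four
#' ordered breakpoints into five half-open classes; the `higher_is_worse`
#' flag sets the orientation (drought indices score worse as they fall).
#' Categorical layers are mapped class-by-class.
#'
#' `default_class_maps()` returns the package-default scoring for the six
#' layers of the composite bean stress score. These defaults are package
#' choices, overrideable in full:
#' * `soil_nutrient`: the five-step constraint ladder from "No constraints"
#'   to "Very severe constraints" maps to 1..5 in order;
#' * `spei` (6-month accumulation, lower is drier/worse): >= 0 scores 1,
#'   then steps at -0.5, -1, -1.5 following the standard SPEI dryness
#'   categories;
#' * `flood` (occurrences per district, 2007-2015): 0 / 1 / 2-3 / 4-5 / >= 6;
#' * `temperature` (mean daily max, deg C): breakpoints 28, 29.5, 32, 35 --
#'   beans grow well to 28, tolerate to 29.5, and temperatures at or above
#'   35 during flowering abort pods, defining the top class;
#' * `deprivation` (0-100 relative index): quintile breakpoints 20/40/60/80;
#' * `ozone_yl` (season-1 percentage yield loss): bands at 5, 10, 16, 22%.
#'
#' @return `default_class_maps()`: named list of class maps. A continuous
#'   class map is `list(breaks = <4 ascending numbers>, higher_is_worse =
#'   <flag>)`; a categorical one is `list(classes = <named integer scores>)`.
#' @export
#' @examples
#' default_class_maps()$temperature
default_class_maps <- function() {
  list(
    soil_nutrient = list(classes = c(
      "No constraints" = 1L, "Slight constraints" = 2L,
      "Moderate constraints" = 3L, "Severe constraints" = 4L,
      "Very severe constraints" = 5L
    )),
    spei = list(breaks = c(-1.5, -1, -0.5, 0), higher_is_worse = FALSE),
    flood = list(breaks = c(1, 2, 4, 6), higher_is_worse = TRUE),
    temperature = list(breaks = c(28, 29.5, 32, 35), higher_is_worse = TRUE),
    deprivation = list(breaks = c(20, 40, 60, 80), higher_is_worse = TRUE),
    ozone_yl = list(breaks = c(5, 10, 16, 22), higher_is_worse = TRUE)
  )
}

#' Soil nutrient constraint ladder
#'
#' The ordered classes of the categorical soil-nutrient stress layer.
#' @return Character vector of the five classes, best to worst.
#' @export
soil_constraint_classes <- function() {
  c("No constraints", "Slight constraints", "Moderate constraints",
    "Severe constraints", "Very severe constraints")
}

#' Score one stress layer on the 1-5 risk scale
#'
#' @param layer A [raster_field()].
#' @param class_map For continuous layers, `list(breaks, higher_is_worse)`
#'   with four ascending breakpoints (half-open classes `[b_k, b_{k+1})`: a
#'   value equal to a breakpoint falls in the class above it); for
#'   categorical layers, `list(classes = named integer vector)` covering
#'   every class. Defaults to the layer's entry in [default_class_maps()]
#'   looked up by `name`.
#' @param name Layer name used for the default lookup.
#' @return A [raster_field()] of integer scores in 1..5 (missing cells stay
#'   missing), with units `"score"`.
#' @export
#' @examples
#' g <- grid_spec(0, 0, 1, 1, 2, 1)
#' tmp <- raster_field(g, matrix(c(25, 36), 1, 2), units = "degC")
#' score_layer(tmp, name = "temperature")$values
score_layer <- function(layer, class_map = NULL, name = NULL) {
  stopifnot(is_raster_field(layer))
  if (is.null(class_map)) {
    if (is.null(name) || !name %in% names(default_class_maps())) {
      stop("supply a class_map or a layer name with a package default")
    }
    class_map <- default_class_maps()[[name]]
  }
  v <- layer$values
  if (layer$kind == "categorical") {
    if (is.null(class_map$classes)) {
      stop("categorical layer needs a class -> score table")
    }
    scores <- class_map$classes
    if (any(scores < 1 | scores > 5)) stop("scores must lie in 1..5")
    present <- unique(v[!is.na(v)])
    uncovered <- setdiff(present, names(scores))
    if (length(uncovered) > 0) {
      stop("class(es) not covered by the score table: ",
           paste(uncovered, collapse = ", "))
    }
    out <- matrix(NA_integer_, nrow(v), ncol(v))
    ok <- !is.na(v)
    out[ok] <- unname(scores[v[ok]])
  } else {
    br <- class_map$breaks
    if (is.null(br) || length(br) != 4 || is.unsorted(br, strictly = TRUE)) {
      stop("continuous class map needs 4 strictly ascending breakpoints")
    }
    hw <- isTRUE(class_map$higher_is_worse)
    out <- matrix(NA_integer_, nrow(v), ncol(v))
    ok <- !is.na(v)
    k <- findInterval(v[ok], br)   # 0..4; value == break -> class above
    out[ok] <- as.integer(if (hw) 1L + k else 5L - k)
  }
  raster_field(layer$grid, out, units = "score")
}

#' Rasterise district flood-occurrence counts by majority area
#'
#' Builds the flood stress layer from district polygons carrying occurrence
#' counts: each grid cell takes the count of the district with the greatest
#' overlap area with the cell footprint (the majority rule shared with
#' [assign_cells()]). Cells overlapping no district are missing.
#'
#' @param districts Named list of district polygons (as in
#'   [assign_cells()]).
#' @param counts Named numeric vector of flood occurrences per district
#'   (non-negative), names matching `districts`.
#' @param grid Target [grid_spec()].
#' @return A [raster_field()] of occurrence counts.
#' @export
flood_layer_from_districts <- function(districts, counts, grid) {
  stopifnot(is_grid_spec(grid))
  if (!setequal(names(districts), names(counts))) {
    stop("district polygon and count names differ")
  }
  if (any(counts < 0)) stop("flood occurrence counts must be non-negative")
  dm <- assign_cells(grid, districts)
  if (all(is.na(dm$assignment))) stop("districts overlap no grid cell")
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  ok <- !is.na(dm$assignment)
  vals[ok] <- unname(counts[dm$assignment[ok]])
  raster_field(grid, vals, units = "occurrences")
}

#' Sum per-layer scores into the composite crop stress score
#'
#' The composite is the plain sum of the per-layer 1-5 scores, so with `n`
#' layers it ranges over `[n, 5n]` (6..30 for the standard six layers). A
#' cell missing in any layer is missing in the composite; per-layer missing
#' counts are attached as attribute `missing_by_layer`.
#'
#' @param scores Named list of score fields from [score_layer()], all on one
#'   grid.
#' @return A [raster_field()] composite with attribute `missing_by_layer`.
#' @export
composite_score <- function(scores) {
  if (length(scores) < 1) stop("at least one score layer is required")
  g <- scores[[1]]$grid
  for (s in scores) {
    stopifnot(is_raster_field(s))
    if (!grids_identical(s$grid, g)) stop("score layers on different grids")
    if (any(s$values < 1 | s$values > 5, na.rm = TRUE) ||
        any(s$values[!is.na(s$values)] %% 1 != 0)) {
      stop("scores must be integers in 1..5")
    }
  }
  total <- Reduce(`+`, lapply(scores, function(s) s$values))
  out <- raster_field(g, total, units = "score")
  attr(out, "missing_by_layer") <-
    vapply(scores, function(s) sum(is.na(s$values)), 0L)
  out
}

#' Score a set of stress layers and build the composite
#'
#' Convenience wrapper: scores each named layer with
#' [default_class_maps()] (entries overridden by `class_maps`) and returns
#' both the per-layer score fields and their composite.
#'
#' @param layers Named list of [raster_field()] stress layers; names must
#'   have a default class map or an override.
#' @param class_maps Optional named list of class-map overrides.
#' @return List with `scores` (named list of score fields) and `composite`.
#' @export
score_stress_layers <- function(layers, class_maps = list()) {
  maps <- utils::modifyList(default_class_maps(), class_maps)
  scores <- purrr::imap(layers, function(l, nm) {
    if (!nm %in% names(maps)) stop("no class map for layer: ", nm)
    score_layer(l, maps[[nm]])
  })
  list(scores = scores, composite = composite_score(scores))
}
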