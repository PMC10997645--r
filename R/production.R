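#' Gridded crop production raster
#'
#' A [raster_field()] of tonnes per cell carrying a year label and a season
#' label (`"annual"` before seasonal splitting; `"season1"`, `"season2"` or
#' `"unimodal"` after). Values are extensive (tonnes per cell), so regridding
#' must use the `sum_conserving` method.
#'
#' @param grid A [grid_spec()].
#' @param values Matrix of tonnes per cell (non-negative where not missing).
#' @param year Year label (e.g. `2015`).
#' @param season `"annual"`, `"season1"`, `"season2"` or `"unimodal"`.
#' @return A `production_raster` (also a `raster_field`).
#' @export
production_raster <- function(grid, values, year,
                              season = c("annual", "season1", "season2",
                                         "unimodal")) {
  season <- match.arg(season)
  if (any(values < 0, na.rm = TRUE)) stop("production must be non-negative")
  out <- raster_field(grid, values, units = "t")
  attr(out, "year") <- year
  attr(out, "season") <- season
  class(out) <- c("production_raster", class(out))
  out
}

#' @export
print.production_raster <- function(x, ...) {
  cat(sprintf("<production_raster> year %s, season %s, total %.6g t\n",
              attr(x, "year"), attr(x, "season"),
              sum(x$values, na.rm = TRUE)))
  NextMethod()
}

#' Derive regional conversion factors from two agricultural surveys
#'
#' Converts a production raster from its base (dataset) year to a target
#' year using how regional survey totals changed between two survey years.
#' The regional total is interpolated linearly in time between the two survey
#' anchors, and the factor is the ratio of the interpolated target-year total
#' to the interpolated base-year total, per region. Regions whose production
#' did not change get a factor of exactly 1.
#'
#' @param survey_early,survey_late Data frames with columns `region`,
#'   `tonnes`: regional totals from the earlier and later surveys. Region
#'   sets must match.
#' @param early_year,late_year Survey years (`early_year < late_year`).
#' @param target_year Year to convert to.
#' @param base_year Year the raster dataset represents.
#' @return Tibble with columns `region`, `factor`.
#' @export
#' @examples
#' derive_conversion_factors(
#'   data.frame(region = "N", tonnes = 100),
#'   data.frame(region = "N", tonnes = 200),
#'   early_year = 2009, late_year = 2018,
#'   target_year = 2015, base_year = 2017
#' )
derive_conversion_factors <- function(survey_early, survey_late,
                                      early_year, late_year,
                                      target_year, base_year) {
  stopifnot(all(c("region", "tonnes") %in% names(survey_early)),
            all(c("region", "tonnes") %in% names(survey_late)),
            early_year < late_year)
  if (!setequal(survey_early$region, survey_late$region)) {
    stop("survey region sets differ")
  }
  if (any(survey_early$tonnes < 0) || any(survey_late$tonnes < 0)) {
    stop("survey production must be non-negative")
  }
  if (any(survey_early$tonnes == 0)) {
    stop("zero early-survey production for region(s): ",
         paste(survey_early$region[survey_early$tonnes == 0], collapse = ", "))
  }
  tbl <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(survey_early), early = "tonnes"),
    dplyr::rename(tibble::as_tibble(survey_late), late = "tonnes"),
    by = "region"
  )
  interp <- function(y) {
    tbl$early + (tbl$late - tbl$early) *
      (y - early_year) / (late_year - early_year)
  }
  at_target <- interp(target_year)
  at_base <- interp(base_year)
  if (any(at_base <= 0) || any(at_target <= 0)) {
    stop("interpolated regional totals must stay positive in the conversion span")
  }
  tibble::tibble(region = tbl$region, factor = at_target / at_base)
}

#' Apply regional conversion factors to a production raster
#'
#' Multiplies each assigned cell's production by the factor of the (parent)
#' region its sub-region belongs to, relabelling the output year. Unassigned
#' cells are left unchanged; their count is reported via a message.
#'
#' @param raster A [production_raster()].
#' @param factors Data frame with columns `region`, `factor` (factors > 0).
#' @param regions A region map on the raster's grid.
#' @param region_lookup Data frame with columns `sub_region`, `region`
#'   mapping sub-regions to the level at which factors are defined.
#' @param target_year Year label for the output.
#' @return A [production_raster()] for `target_year`.
#' @export
apply_conversion <- function(raster, factors, regions, region_lookup,
                             target_year) {
  stopifnot(inherits(raster, "production_raster"), is_region_map(regions),
            all(c("region", "factor") %in% names(factors)),
            all(c("sub_region", "region") %in% names(region_lookup)))
  if (!grids_identical(raster$grid, regions$grid)) {
    stop("raster and regions are on different grids")
  }
  if (any(factors$factor <= 0)) stop("conversion factors must be positive")
  lut <- stats::setNames(region_lookup$region, region_lookup$sub_region)
  needed_sub <- unique(regions$assignment[!is.na(regions$assignment)])
  unmapped <- setdiff(needed_sub, names(lut))
  if (length(unmapped) > 0) {
    stop("no region mapping for sub-region(s): ",
         paste(unmapped, collapse = ", "))
  }
  fmap <- stats::setNames(factors$factor, factors$region)
  needed_reg <- unique(unname(lut[needed_sub]))
  missing_f <- setdiff(needed_reg, names(fmap))
  if (length(missing_f) > 0) {
    stop("missing conversion factor for region(s): ",
         paste(missing_f, collapse = ", "))
  }
  cellf <- matrix(1, raster$grid$n_rows, raster$grid$n_cols)
  assigned <- !is.na(regions$assignment)
  cellf[assigned] <- unname(fmap[unname(lut[regions$assignment[assigned]])])
  n_un <- sum(!assigned)
  if (n_un > 0) {
    message(n_un, " unassigned cell(s) left unconverted")
  }
  production_raster(raster$grid, raster$values * cellf,
                    year = target_year, season = attr(raster, "season"))
}

#' Default seasonal production splits for the Ugandan bean assessment
#'
#' Nationally about 60% of annual bean production is harvested in the first
#' growing season and 40% in the second; three sub-regions deviate enough to
#' warrant overrides (West Nile 30:70, Lango 69:31, North Buganda 61:39), and
#' Karamoja's unimodal rainfall routes all production to its single window.
#'
#' @param sub_regions Character vector of sub-region names.
#' @param unimodal Names (subset of `sub_regions`) with a single season.
#' @param overrides Optional data frame `sub_region`, `share_season1`,
#'   `share_season2` replacing the national default for listed sub-regions.
#' @param default_share_season1 National season-1 share.
#' @return Tibble `sub_region`, `share_season1`, `share_season2`, `unimodal`.
#' @export
seasonal_split_table <- function(sub_regions, unimodal = character(),
                                 overrides = NULL,
                                 default_share_season1 = 0.6) {
  stopifnot(default_share_season1 >= 0, default_share_season1 <= 1,
            all(unimodal %in% sub_regions))
  tbl <- tibble::tibble(
    sub_region = sub_regions,
    share_season1 = default_share_season1,
    share_season2 = 1 - default_share_season1,
    unimodal = sub_regions %in% unimodal
  )
  if (!is.null(overrides)) {
    stopifnot(all(c("sub_region", "share_season1", "share_season2") %in%
                    names(overrides)))
    idx <- match(overrides$sub_region, tbl$sub_region)
    if (any(is.na(idx))) stop("override for unknown sub-region")
    tbl$share_season1[idx] <- overrides$share_season1
    tbl$share_season2[idx] <- overrides$share_season2
  }
  tbl$share_season1[tbl$unimodal] <- 1
  tbl$share_season2[tbl$unimodal] <- 0
  validate_split_table(tbl)
  tbl
}

validate_split_table <- function(splits) {
  stopifnot(all(c("sub_region", "share_season1", "share_season2") %in%
                  names(splits)))
  if (any(splits$share_season1 < 0 | splits$share_season2 < 0)) {
    stop("seasonal shares must be non-negative")
  }
  bad <- abs(splits$share_season1 + splits$share_season2 - 1) > 1e-9
  if (any(bad)) {
    stop("seasonal shares must sum to 1; offending sub-region(s): ",
         paste(splits$sub_region[bad], collapse = ", "))
  }
  invisible(splits)
}

#' Split annual production into the two growing seasons
#'
#' Multiplies each cell's annual tonnes by its sub-region's seasonal shares.
#' The two outputs sum to the input exactly, cell by cell. Unimodal
#' sub-regions carry shares (1, 0): all their production appears in the
#' season-1 raster, to be assessed against their own accumulation window.
#' Unassigned cells get the national residual treatment of shares (NA) and
#' become missing in both outputs.
#'
#' @param raster An annual [production_raster()].
#' @param splits A split table from [seasonal_split_table()].
#' @param regions A region map on the raster's grid.
#' @return List with elements `season1`, `season2` ([production_raster()]s).
#' @export
split_seasons <- function(raster, splits, regions) {
  stopifnot(inherits(raster, "production_raster"), is_region_map(regions))
  if (attr(raster, "season") != "annual") {
    stop("raster is already seasonal; splitting is only defined for annual rasters")
  }
  if (!grids_identical(raster$grid, regions$grid)) {
    stop("raster and regions are on different grids")
  }
  validate_split_table(splits)
  needed <- unique(regions$assignment[!is.na(regions$assignment)])
  missing_s <- setdiff(needed, splits$sub_region)
  if (length(missing_s) > 0) {
    stop("no seasonal split for sub-region(s): ",
         paste(missing_s, collapse = ", "))
  }
  s1 <- stats::setNames(splits$share_season1, splits$sub_region)
  share1 <- matrix(NA_real_, raster$grid$n_rows, raster$grid$n_cols)
  assigned <- !is.na(regions$assignment)
  share1[assigned] <- unname(s1[regions$assignment[assigned]])
  list(
    season1 = production_raster(raster$grid, raster$values * share1,
                                year = attr(raster, "year"),
                                season = "season1"),
    season2 = production_raster(raster$grid, raster$values * (1 - share1),
                                year = attr(raster, "year"),
                                season = "season2")
  )
}
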