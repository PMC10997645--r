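#' Zonal statistics of a raster field over sub-regions
#'
#' Computes one statistic per sub-region over the non-missing cells assigned
#' to it, optionally restricted by a mask. A region with no contributing
#' cells is reported with a missing value (never zero): missingness must stay
#' visible through aggregation.
#'
#' @param field A [raster_field()] (continuous).
#' @param regions A region map from [assign_cells()] on the same grid.
#' @param stat One of `"mean"`, `"sum"`, `"min"`, `"max"`.
#' @param mask Optional [raster_field()] or logical matrix on the same grid;
#'   cells where the mask is missing, `NA` or zero/`FALSE` are excluded.
#' @return Tibble with columns `sub_region`, `stat`, `value`, `n_cells`
#'   (number of contributing cells).
#' @export
#' @examples
#' g <- grid_spec(0, 0, 1, 1, 2, 1)
#' rm <- assign_cells(g, list(A = list(rect_polygon(0, 2, 0, 1))))
#' zonal_stat(raster_field(g, matrix(c(10, 20), 1, 2)), rm, "mean")
zonal_stat <- function(field, regions, stat = c("mean", "sum", "min", "max"),
                       mask = NULL) {
  stat <- match.arg(stat)
  stopifnot(is_raster_field(field), is_region_map(regions))
  if (!grids_identical(field$grid, regions$grid)) {
    stop("field and regions are on different grids")
  }
  include <- !is.na(regions$assignment) & !is.na(field$values)
  if (!is.null(mask)) {
    mv <- if (is_raster_field(mask)) mask$values else mask
    if (!all(dim(mv) == dim(field$values))) stop("mask grid mismatch")
    include <- include & !is.na(mv) & (mv != 0)
  }
  fn <- switch(stat, mean = mean, sum = sum, min = min, max = max)
  tibble::tibble(
    sub_region = regions$assignment[include],
    value = field$values[include]
  ) |>
    dplyr::group_by(.data$sub_region) |>
    dplyr::summarise(value = fn(.data$value), n_cells = dplyr::n(),
                     .groups = "drop") |>
    # regions present in the map but with no contributing cells -> NA rows
    dplyr::right_join(
      tibble::tibble(sub_region = names(regions$polygons)),
      by = "sub_region"
    ) |>
    dplyr::mutate(stat = stat,
                  n_cells = dplyr::coalesce(.data$n_cells, 0L)) |>
    dplyr::select("sub_region", "stat", "value", "n_cells") |>
    dplyr::arrange(.data$sub_region)
}
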