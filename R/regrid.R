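#' Regrid a raster field onto another grid
#'
#' Transfers a field between grids of different resolution and/or alignment.
#' Methods:
#' \describe{
#'   \item{`area_weighted_mean`}{target value = overlap-area-weighted mean of
#'     the non-missing source values under the target cell. The conventional
#'     choice for intensive quantities (indices, temperatures).}
#'   \item{`majority`}{class with the greatest overlap area (categorical
#'     fields only).}
#'   \item{`sum_conserving`}{each source cell's value is distributed over the
#'     target cells in proportion to overlap area, so the total of an
#'     extensive quantity (e.g. tonnes) over the shared domain is conserved.}
#'   \item{`nearest`}{value of the source cell containing the target cell's
#'     centre; the default way a coarse exposure field is sampled onto a fine
#'     production grid.}
#' }
#' Missing source cells contribute nothing; a target cell with no
#' contributing source is missing.
#'
#' @param field A [raster_field()].
#' @param target A [grid_spec()] overlapping the source grid.
#' @param method One of `"area_weighted_mean"`, `"majority"`,
#'   `"sum_conserving"`, `"nearest"`.
#' @return A [raster_field()] on `target`.
#' @export
#' @examples
#' src <- raster_field(grid_spec(0, 0, 1, 1, 2, 2), matrix(1:4, 2, 2))
#' regrid(src, grid_spec(0, 0, 2, 2, 1, 1), "area_weighted_mean")$values
regrid <- function(field, target,
                   method = c("area_weighted_mean", "majority",
                              "sum_conserving", "nearest")) {
  method <- match.arg(method)
  stopifnot(is_raster_field(field), is_grid_spec(target))
  src <- field$grid
  se <- grid_extent(src); te <- grid_extent(target)
  if (se["lon_min"] >= te["lon_max"] || te["lon_min"] >= se["lon_max"] ||
      se["lat_min"] >= te["lat_max"] || te["lat_min"] >= se["lat_max"]) {
    stop("source and target grids are disjoint")
  }
  if (method == "majority" && field$kind != "categorical") {
    stop("majority regridding requires a categorical field")
  }
  if (method != "majority" && field$kind == "categorical" && method != "nearest") {
    stop("method '", method, "' is not defined for categorical fields")
  }

  if (method == "nearest") {
    cc <- cell_centres(target)
    si <- lon_to_col(src, cc$lon)
    sj <- lat_to_row(src, cc$lat)
    empty <- if (field$kind == "categorical") NA_character_ else NA_real_
    vals <- rep(empty, nrow(cc))
    ok <- !is.na(si) & !is.na(sj)
    vals[ok] <- field$values[cbind(sj[ok] + 1L, si[ok] + 1L)]
    m <- matrix(empty, target$n_rows, target$n_cols)
    m[cbind(cc$row + 1L, cc$col + 1L)] <- vals
    return(raster_field(target, m, units = field$units, kind = field$kind,
                        levels = field$levels))
  }

  # Per-axis overlap lengths between source and target cell intervals;
  # the overlap area of (source k, target i) factorises as wx * wy.
  axis_overlap <- function(o_s, d_s, n_s, o_t, d_t, n_t) {
    # returns list over target index: integer source indices + overlap widths
    lapply(seq_len(n_t) - 1L, function(i) {
      t0 <- o_t + i * d_t; t1 <- t0 + d_t
      k0 <- max(0L, floor((t0 - o_s) / d_s))
      k1 <- min(n_s - 1L, ceiling((t1 - o_s) / d_s) - 1L)
      if (k1 < k0) return(list(idx = integer(0), w = numeric(0)))
      ks <- k0:k1
      s0 <- o_s + ks * d_s; s1 <- s0 + d_s
      w <- pmin(t1, s1) - pmax(t0, s0)
      keep <- w > 0
      list(idx = ks[keep], w = w[keep])
    })
  }
  ox <- axis_overlap(src$origin_lon, src$cell_size_lon, src$n_cols,
                     target$origin_lon, target$cell_size_lon, target$n_cols)
  oy <- axis_overlap(src$origin_lat, src$cell_size_lat, src$n_rows,
                     target$origin_lat, target$cell_size_lat, target$n_rows)
  src_area <- src$cell_size_lon * src$cell_size_lat

  empty <- if (field$kind == "categorical") NA_character_ else NA_real_
  out <- matrix(empty, target$n_rows, target$n_cols)
  for (j in seq_len(target$n_rows)) {
    ry <- oy[[j]]
    if (length(ry$idx) == 0) next
    for (i in seq_len(target$n_cols)) {
      rx <- ox[[i]]
      if (length(rx$idx) == 0) next
      vals <- field$values[ry$idx + 1L, rx$idx + 1L, drop = FALSE]
      w <- outer(ry$w, rx$w)
      ok <- !is.na(vals)
      if (!any(ok)) next
      out[j, i] <- switch(method,
        area_weighted_mean = sum(w[ok] * vals[ok]) / sum(w[ok]),
        sum_conserving = sum(vals[ok] * w[ok] / src_area),
        majority = {
          tb <- tapply(w[ok], vals[ok], sum)
          names(tb)[which.max(tb)]
        }
      )
    }
  }
  raster_field(target, out, units = field$units, kind = field$kind,
               levels = field$levels)
}
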