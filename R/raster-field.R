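#' Gridded field of values on a grid_spec
#'
#' The package's raster container: a numeric (or factor-coded categorical)
#' matrix of per-cell values on a [grid_spec()]. Values are stored as an
#' `n_rows x n_cols` matrix with `values[j + 1, i + 1]` the value of cell
#' `(i, j)` (0-based column `i`, row `j`, row 0 southernmost). `NA` marks a
#' missing cell; missingness propagates through every operation and is never
#' silently replaced by zero.
#'
#' @param grid A [grid_spec()].
#' @param values Matrix `n_rows x n_cols` (or a scalar, recycled). For
#'   categorical fields, a character matrix whose entries are drawn from
#'   `levels`.
#' @param units Free-text units label.
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels For categorical fields, the ordered vector of legal classes.
#'
#' @return A `raster_field` object.
#' @export
#' @examples
#' g <- grid_spec(0, 0, 1, 1, 2, 2)
#' raster_field(g, matrix(1:4, 2, 2), units = "t")
raster_field <- function(grid, values, units = "",
                         kind = c("continuous", "categorical"),
                         levels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is_grid_spec(grid))
  if (length(values) == 1L) {
    values <- matrix(values, grid$n_rows, grid$n_cols)
  }
  stopifnot(is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (kind == "categorical") {
    if (is.null(levels)) stop("categorical fields must enumerate their `levels`")
    bad <- setdiff(unique(values[!is.na(values)]), levels)
    if (length(bad) > 0) {
      stop("values outside declared levels: ", paste(bad, collapse = ", "))
    }
  } else {
    stopifnot(is.numeric(values) || all(is.na(values)))
  }
  structure(
    list(grid = grid, values = values, units = units, kind = kind,
         levels = levels),
    class = "raster_field"
  )
}

is_raster_field <- function(x) inherits(x, "raster_field")

#' @export
print.raster_field <- function(x, ...) {
  n_na <- sum(is.na(x$values))
  cat(sprintf("<raster_field> %s kind=%s units='%s' (%d missing cells)\n",
              format(x$grid), x$kind, x$units, n_na))
  if (x$kind == "continuous") {
    rng <- suppressWarnings(range(x$values, na.rm = TRUE))
    if (all(is.finite(rng))) cat(sprintf("  range [%.6g, %.6g]\n", rng[1], rng[2]))
  } else {
    cat("  classes:", paste(x$levels, collapse = " < "), "\n")
  }
  invisible(x)
}

#' Tidy a raster field into a per-cell tibble
#'
#' One row per grid cell with 0-based `col`/`row` indices, cell-centre
#' coordinates and the cell value (`NA` for missing cells).
#'
#' @param x A [raster_field()].
#' @param ... Unused.
#' @return A tibble with columns `col`, `row`, `lon`, `lat`, `value`.
#' @method tidy raster_field
#' @export
tidy.raster_field <- function(x, ...) {
  cc <- cell_centres(x$grid)
  cc$value <- x$values[cbind(cc$row + 1L, cc$col + 1L)]
  cc
}

#' Build a raster field from a per-cell tibble
#'
#' Inverse of [tidy.raster_field()]: takes a data frame with 0-based
#' `col`/`row` indices and a `value` column. Cells absent from the data frame
#' are missing.
#'
#' @param grid A [grid_spec()].
#' @param df Data frame with columns `col`, `row`, `value`.
#' @inheritParams raster_field
#' @return A [raster_field()].
#' @export
raster_from_table <- function(grid, df, units = "", kind = "continuous",
                              levels = NULL) {
  stopifnot(all(c("col", "row", "value") %in% names(df)))
  if (any(df$col < 0 | df$col >= grid$n_cols |
          df$row < 0 | df$row >= grid$n_rows)) {
    stop("cell indices outside grid")
  }
  empty <- if (kind == "categorical") NA_character_ else NA_real_
  m <- matrix(empty, grid$n_rows, grid$n_cols)
  m[cbind(df$row + 1L, df$col + 1L)] <- df$value
  raster_field(grid, m, units = units, kind = kind, levels = levels)
}

#' Plot a raster field
#'
#' @param object A [raster_field()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot raster_field
#' @export
autoplot.raster_field <- function(object, ...) {
  df <- tidy.raster_field(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = object$units)
  if (object$kind == "continuous") p <- p + ggplot2::scale_fill_viridis_c(na.value = "grey90")
  p
}

# Elementwise transform keeping grid/units metadata.
map_raster <- function(field, f, units = field$units) {
  out <- field
  out$values <- f(field$values)
  out$units <- units
  out
}
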