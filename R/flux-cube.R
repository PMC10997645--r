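#' Gridded time series of stomatal ozone flux or daily dose increments
#'
#' The exposure input. Two modes:
#' \describe{
#'   \item{`daily`}{`values` is an array `n_days x n_rows x n_cols` of daily
#'     phytotoxic-ozone-dose increments, mmol m^-2 d^-1. This is the primary
#'     path: chemical-transport models that embed a stomatal-exchange scheme
#'     emit daily dose increments directly.}
#'   \item{`hourly`}{`values` is an array `n_days x 24 x n_rows x n_cols` of
#'     stomatal ozone flux, nmol m^-2 s^-1, from which daily increments are
#'     derived with [hourly_to_daily_pod()].}
#' }
#'
#' @param grid A [grid_spec()].
#' @param dates `Date` vector, strictly increasing, one entry per day.
#' @param values Array as described above; non-negative where not missing.
#' @param mode `"daily"` or `"hourly"`.
#' @return A `flux_cube` object.
#' @export
flux_cube <- function(grid, dates, values, mode = c("daily", "hourly")) {
  mode <- match.arg(mode)
  stopifnot(is_grid_spec(grid), inherits(dates, "Date"))
  if (any(duplicated(dates)) || is.unsorted(dates, strictly = TRUE)) {
    stop("time axis must be strictly increasing with no duplicate stamps")
  }
  dm <- dim(values)
  if (mode == "daily") {
    stopifnot(length(dm) == 3, dm[1] == length(dates),
              dm[2] == grid$n_rows, dm[3] == grid$n_cols)
  } else {
    stopifnot(length(dm) == 4, dm[1] == length(dates), dm[2] == 24,
              dm[3] == grid$n_rows, dm[4] == grid$n_cols)
  }
  if (any(values < 0, na.rm = TRUE)) stop("flux values must be non-negative")
  structure(
    list(grid = grid, dates = dates, values = values, mode = mode),
    class = "flux_cube"
  )
}

is_flux_cube <- function(x) inherits(x, "flux_cube")

#' @export
print.flux_cube <- function(x, ...) {
  cat(sprintf("<flux_cube:%s> %s, %d days (%s .. %s)\n", x$mode,
              format(x$grid), length(x$dates),
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' Tidy a flux cube into a long per-day per-cell tibble
#'
#' @param x A [flux_cube()] (daily mode).
#' @param ... Unused.
#' @return Tibble with columns `date`, `col`, `row`, `value`.
#' @method tidy flux_cube
#' @export
tidy.flux_cube <- function(x, ...) {
  if (x$mode != "daily") stop("tidy() supports daily-mode cubes")
  g <- x$grid
  tidyr::expand_grid(
    date = x$dates,
    row = seq_len(g$n_rows) - 1L,
    col = seq_len(g$n_cols) - 1L
  ) |>
    dplyr::mutate(value = as.vector(aperm(x$values, c(3, 2, 1))))
}

# day-of-year (1..366)
julian_day <- function(dates) as.POSIXlt(dates)$yday + 1L
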