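#' Growing-season accumulation windows
#'
#' A season window is a named inclusive range of Julian days (day-of-year).
#' `season_window()` builds one; `season_presets()` returns the three 90-day
#' windows used for the Ugandan bean assessment: season 1 (April-June, days
#' 91-180), season 2 (mid-September to mid-December, days 257-346) and the
#' single unimodal window for Karamoja (July-September, days 182-271). Each
#' spans the ozone-sensitive period of roughly anthesis to the end of grain
#' fill, placed before the harvest of that season.
#'
#' @param name Window label.
#' @param start_day,end_day Inclusive Julian days, `1 <= start <= end <= 366`.
#' @return A `season_window` (list with `name`, `start_day`, `end_day`);
#'   `season_presets()` returns a named list of three.
#' @export
#' @examples
#' season_presets()$season1
season_window <- function(name, start_day, end_day) {
  stopifnot(start_day >= 1, end_day >= start_day, end_day <= 366)
  structure(list(name = name, start_day = as.integer(start_day),
                 end_day = as.integer(end_day)),
            class = "season_window")
}

#' @rdname season_window
#' @export
season_presets <- function() {
  list(
    season1 = season_window("season1", 91L, 180L),
    season2 = season_window("season2", 257L, 346L),
    karamoja = season_window("karamoja", 182L, 271L)
  )
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("<season_window> %s: days %d-%d (%d days)\n", x$name,
              x$start_day, x$end_day, x$end_day - x$start_day + 1L))
  invisible(x)
}

#' Integrate hourly stomatal flux into daily dose increments
#'
#' Applies the phytotoxic-dose threshold hour by hour: each hour contributes
#' `max(flux - threshold, 0) * 3600 * 1e-6` mmol m^-2 (nmol -> mmol and
#' seconds per hour), and the contributions are summed per day. The default
#' threshold of 3 nmol m^-2 s^-1 is the POD3 convention. Hours that are
#' missing contribute nothing; a day with all 24 hours missing is missing.
#' No daylight criterion is applied here — mask hours upstream if one is
#' wanted.
#'
#' @param cube An hourly-mode [flux_cube()], nmol m^-2 s^-1.
#' @param threshold Flux threshold, nmol m^-2 s^-1, non-negative.
#' @return A daily-mode [flux_cube()] of increments, mmol m^-2 d^-1.
#' @export
hourly_to_daily_pod <- function(cube, threshold = 3) {
  stopifnot(is_flux_cube(cube))
  if (cube$mode != "hourly") stop("cube is not in hourly-flux mode")
  stopifnot(threshold >= 0)
  exceed <- pmax(cube$values - threshold, 0) * 3600 * 1e-6
  daily <- apply(exceed, c(1, 3, 4), function(h) {
    if (all(is.na(h))) NA_real_ else sum(h, na.rm = TRUE)
  })
  flux_cube(cube$grid, cube$dates, daily, mode = "daily")
}

#' Accumulate daily dose increments over a season window
#'
#' Sums the per-cell daily increments over all days of `window` (inclusive)
#' in calendar year `year`, producing the seasonal accumulated phytotoxic
#' ozone dose. The cube must supply every day of the window; days that are
#' present but missing for some cells are handled per `missing`:
#' \describe{
#'   \item{`error`}{any missing cell-day aborts (the loud default);}
#'   \item{`skip`}{missing days are dropped from the cell's sum (a cell with
#'     no valid day is missing);}
#'   \item{`scale`}{the partial sum is rescaled by
#'     `window length / valid days`, an unbiased patch when missingness is
#'     unstructured.}
#' }
#'
#' @param cube A daily-mode [flux_cube()], mmol m^-2 d^-1.
#' @param window A [season_window()].
#' @param year Calendar year to accumulate within.
#' @param missing Missing-day policy, see above.
#' @return A `pod_field`: a [raster_field()] (mmol m^-2) with the window and
#'   year recorded in attributes `window` and `year`.
#' @export
#' @examples
#' g <- grid_spec(0, 0, 1, 1, 1, 1)
#' d <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
#' cube <- flux_cube(g, d, array(0.1, c(length(d), 1, 1)))
#' accumulate_pod(cube, season_presets()$season1, 2015)$values  # 9.0
accumulate_pod <- function(cube, window, year,
                           missing = c("error", "skip", "scale")) {
  missing <- match.arg(missing)
  stopifnot(is_flux_cube(cube), inherits(window, "season_window"))
  if (cube$mode != "daily") stop("cube is not in daily-increment mode")
  yr <- as.integer(format(cube$dates, "%Y"))
  jd <- julian_day(cube$dates)
  sel <- which(yr == year & jd >= window$start_day & jd <= window$end_day)
  want <- window$start_day:window$end_day
  have <- jd[sel]
  if (!all(want %in% have)) {
    miss <- setdiff(want, have)
    stop(sprintf("cube is missing %d window day(s) for %d: days %s",
                 length(miss), year,
                 paste(utils::head(miss, 10), collapse = ", ")))
  }
  slab <- cube$values[sel, , , drop = FALSE]
  n_window <- length(want)
  valid <- apply(!is.na(slab), c(2, 3), sum)
  total <- apply(slab, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  })
  if (missing == "error" && any(valid < n_window)) {
    stop(sprintf("%d cell(s) have missing days inside the window; %s",
                 sum(valid < n_window),
                 "use missing = 'skip' or 'scale' to accept them"))
  }
  if (missing == "scale") {
    scl <- ifelse(valid > 0, n_window / valid, NA_real_)
    total <- total * scl
  }
  out <- raster_field(cube$grid, total, units = "mmol m-2")
  attr(out, "window") <- window
  attr(out, "year") <- year
  class(out) <- c("pod_field", class(out))
  out
}

#' @export
print.pod_field <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<pod_field> window %s (days %d-%d), year %s\n",
              w$name, w$start_day, w$end_day, attr(x, "year")))
  NextMethod()
}
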