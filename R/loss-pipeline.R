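#' Relative yield from percentage yield loss
#'
#' `relative_yield(yl)` returns the fraction of the reference yield realised
#' under a given percentage loss, `1 - yl/100`. Inputs must lie in
#' `[0, 99.9]`: the yield-loss clamp guarantees the downstream division by
#' relative yield is always defined.
#'
#' @param yield_loss_pct Percentage yield loss in `[0, 99.9]` (vectorised;
#'   `NA` passes through).
#' @return Fraction(s) in `(0.001, 1]`.
#' @export
#' @examples
#' relative_yield(c(0, 20, 50))
relative_yield <- function(yield_loss_pct) {
  ok <- is.na(yield_loss_pct) |
    (yield_loss_pct >= 0 & yield_loss_pct <= 99.9)
  if (!all(ok)) stop("yield loss must be within [0, 99.9] percent")
  1 - yield_loss_pct / 100
}

#' Production loss from observed production and yield loss
#'
#' The tonnage that would have been harvested absent ozone, minus what was
#' harvested: `loss = production / relative_yield - production`, i.e.
#' `production * yl / (100 - yl)`. Observed production is what survived the
#' loss, so the loss is measured against the inflated pre-loss potential.
#'
#' The package reads relative yield as `1 - yl/100`; an alternative literal
#' reciprocal form (`RY = 1/(yl/100)`) circulates in print but yields
#' negative, dimensionally inconsistent losses — it is available behind
#' `literal = TRUE` purely for auditing that discrepancy.
#'
#' @param production_t Observed production, tonnes (non-negative,
#'   vectorised).
#' @param yield_loss_pct Percentage yield loss in `[0, 99.9]`.
#' @param literal If `TRUE`, use the literal reciprocal relative-yield form
#'   (audit only).
#' @return Tonnes lost (same length as inputs).
#' @export
#' @examples
#' production_loss(100, 20)  # 25
#' production_loss(80, 50)   # 80
production_loss <- function(production_t, yield_loss_pct, literal = FALSE) {
  if (any(production_t < 0, na.rm = TRUE)) {
    stop("production must be non-negative")
  }
  if (any(yield_loss_pct >= 100, na.rm = TRUE)) {
    stop("yield loss must be below 100 percent")
  }
  if (literal) {
    ry <- 1 / (yield_loss_pct / 100)
    return(production_t / ry - production_t)
  }
  production_t / relative_yield(yield_loss_pct) - production_t
}

#' Run the full dose-to-loss assessment
#'
#' Applies the flux-effect model to each season's accumulated dose field,
#' converts the per-cell percentage losses and seasonal production to
#' production losses, and aggregates to sub-region, region and national
#' rows.
#'
#' Aggregation rules:
#' * sub-region mean yield loss is the unweighted mean over grid cells that
#'   have production data — including zero-production cells — so the map of
#'   potential risk is not masked by where production happens to be;
#' * production losses are summed over cells with production > 0;
#' * national rows aggregate at the cell level (mean over all contributing
#'   cells, sum of all losses), not as a mean of sub-region means;
#' * unimodal sub-regions are assessed once, against their own window, and
#'   reported in the season-1 position; their season-2 row is missing.
#'
#' @param pod Named list of `pod_field`s on the production grid: `season1`,
#'   `season2`, and one entry per unimodal window named as referenced by
#'   `unimodal_windows` (e.g. `unimodal`).
#' @param model A `flux_effect_model`.
#' @param production List with `season1` and `season2`
#'   [production_raster()]s (from [split_seasons()]).
#' @param regions Region map on the same grid.
#' @param region_lookup Optional data frame `sub_region`, `region` adding a
#'   parent-region column to the output.
#' @param unimodal_windows Named character vector mapping unimodal
#'   sub-region name -> name of its entry in `pod` (e.g.
#'   `c(Karamoja = "unimodal")`).
#' @return An `ozone_assessment`: list with `table` (tibble: `sub_region`,
#'   `region`, `season`, `mean_yield_loss_pct`, `production_t`,
#'   `production_loss_t`, `n_cells`) including per-sub-region `annual` rows
#'   and `National` rows, and `rasters` (per-season yield-loss and
#'   production-loss fields).
#' @export
run_assessment <- function(pod, model, production, regions,
                           region_lookup = NULL,
                           unimodal_windows = character()) {
  stopifnot(is_region_map(regions),
            all(c("season1", "season2") %in% names(pod)),
            all(c("season1", "season2") %in% names(production)))
  for (s in c("season1", "season2")) {
    if (attr(production[[s]], "season") != s) {
      stop("production raster labelled '", attr(production[[s]], "season"),
           "' supplied for ", s)
    }
    if (!grids_identical(production[[s]]$grid, regions$grid) ||
        !grids_identical(pod[[s]]$grid, regions$grid)) {
      stop("all inputs must share the region grid (regrid first)")
    }
  }
  if (length(unimodal_windows) > 0) {
    missing_w <- setdiff(unname(unimodal_windows), names(pod))
    if (length(missing_w) > 0) {
      stop("no dose field supplied for unimodal window(s): ",
           paste(missing_w, collapse = ", "))
    }
  }

  assignment <- regions$assignment
  uni_cells <- !is.na(assignment) &
    assignment %in% names(unimodal_windows)

  season_cellwise <- function(s) {
    yl <- yield_loss(pod[[s]], model)$values
    if (s == "season1" && any(uni_cells)) {
      for (sr in names(unimodal_windows)) {
        w <- unimodal_windows[[sr]]
        ylu <- yield_loss(pod[[w]], model)$values
        sel <- !is.na(assignment) & assignment == sr
        yl[sel] <- ylu[sel]
      }
    }
    if (s == "season2") yl[uni_cells] <- NA_real_
    prod <- production[[s]]$values
    if (s == "season2") prod[uni_cells] <- NA_real_
    loss <- matrix(NA_real_, nrow(yl), ncol(yl))
    ok <- !is.na(prod) & !is.na(yl)
    loss[ok] <- production_loss(prod[ok], yl[ok])
    list(yl = yl, prod = prod, loss = loss)
  }

  cw <- list(season1 = season_cellwise("season1"),
             season2 = season_cellwise("season2"))

  summarise_season <- function(s) {
    cz <- cw[[s]]
    contributing <- !is.na(assignment) & !is.na(cz$prod) & !is.na(cz$yl)
    tibble::tibble(
      sub_region = assignment[contributing],
      yl = cz$yl[contributing],
      prod = cz$prod[contributing],
      loss = cz$loss[contributing]
    ) |>
      dplyr::group_by(.data$sub_region) |>
      dplyr::summarise(
        season = s,
        mean_yield_loss_pct = mean(.data$yl),
        production_t = sum(.data$prod),
        production_loss_t = sum(.data$loss[.data$prod > 0]),
        n_cells = dplyr::n(),
        .groups = "drop"
      )
  }

  tbl <- dplyr::bind_rows(summarise_season("season1"),
                          summarise_season("season2"))

  # season-2 rows for unimodal sub-regions: reported missing, as the season
  # does not exist there
  if (length(unimodal_windows) > 0) {
    uni_rows <- tibble::tibble(
      sub_region = names(unimodal_windows), season = "season2",
      mean_yield_loss_pct = NA_real_, production_t = 0,
      production_loss_t = NA_real_, n_cells = 0L
    )
    tbl <- tbl |>
      dplyr::filter(!(.data$season == "season2" &
                        .data$sub_region %in% names(unimodal_windows))) |>
      dplyr::bind_rows(uni_rows)
  }

  if (!is.null(region_lookup)) {
    tbl <- dplyr::left_join(
      tbl, tibble::as_tibble(region_lookup)[, c("sub_region", "region")],
      by = "sub_region"
    )
  } else {
    tbl$region <- NA_character_
  }

  national <- purrr::map_dfr(c("season1", "season2"), function(s) {
    cz <- cw[[s]]
    contributing <- !is.na(assignment) & !is.na(cz$prod) & !is.na(cz$yl)
    tibble::tibble(
      sub_region = "National", region = NA_character_, season = s,
      mean_yield_loss_pct = mean(cz$yl[contributing]),
      production_t = sum(cz$prod[contributing]),
      production_loss_t = sum(cz$loss[contributing & cz$prod > 0]),
      n_cells = sum(contributing)
    )
  })

  tbl <- dplyr::bind_rows(tbl, national)
  tbl <- dplyr::bind_rows(tbl, annual_rows(tbl))
  tbl <- dplyr::select(tbl, "sub_region", "region", "season",
                       "mean_yield_loss_pct", "production_t",
                       "production_loss_t", "n_cells") |>
    dplyr::arrange(.data$sub_region != "National", .data$sub_region,
                   .data$season)

  mk_field <- function(vals, units) raster_field(regions$grid, vals, units)
  structure(
    list(
      table = tbl,
      rasters = list(
        yield_loss = list(season1 = mk_field(cw$season1$yl, "%"),
                          season2 = mk_field(cw$season2$yl, "%")),
        production_loss = list(season1 = mk_field(cw$season1$loss, "t"),
                               season2 = mk_field(cw$season2$loss, "t"))
      ),
      model = model
    ),
    class = "ozone_assessment"
  )
}

# Annual rows: per sub_region (and National), sum of the season rows.
annual_rows <- function(tbl) {
  tbl |>
    dplyr::filter(.data$season %in% c("season1", "season2")) |>
    dplyr::group_by(.data$sub_region, .data$region) |>
    dplyr::summarise(
      season = "annual",
      mean_yield_loss_pct = NA_real_,
      production_t = sum(.data$production_t, na.rm = TRUE),
      production_loss_t = sum(.data$production_loss_t, na.rm = TRUE),
      n_cells = max(.data$n_cells),
      .groups = "drop"
    )
}

#' Aggregate a long table of seasonal production losses
#'
#' Takes per-sub-region seasonal rows (columns `sub_region`, `season` in
#' `"season1"`/`"season2"`, `production_loss_t`, optionally `region` and
#' `production_t`) and appends the aggregate rows the assessment reports:
#' an `annual` row per sub-region (season sum, missing seasons skipped) and
#' `National` rows per season and annual (sums over sub-regions). This is
#' the same aggregation [run_assessment()] applies to its cell-level
#' results, exposed for externally supplied loss tables.
#'
#' @param tbl Long tibble of seasonal per-sub-region losses.
#' @return The input plus the aggregate rows.
#' @export
#' @examples
#' aggregate_losses(uganda_bean_losses())
aggregate_losses <- function(tbl) {
  stopifnot(all(c("sub_region", "season", "production_loss_t") %in%
                  names(tbl)))
  tbl <- tibble::as_tibble(tbl)
  if (!"region" %in% names(tbl)) tbl$region <- NA_character_
  if (!"production_t" %in% names(tbl)) tbl$production_t <- NA_real_
  if (!"mean_yield_loss_pct" %in% names(tbl)) {
    tbl$mean_yield_loss_pct <- NA_real_
  }
  if (!"n_cells" %in% names(tbl)) tbl$n_cells <- NA_integer_
  national <- tbl |>
    dplyr::filter(.data$season %in% c("season1", "season2")) |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(
      sub_region = "National", region = NA_character_,
      mean_yield_loss_pct = NA_real_,
      production_t = sum(.data$production_t, na.rm = TRUE),
      production_loss_t = sum(.data$production_loss_t, na.rm = TRUE),
      n_cells = NA_integer_,
      .groups = "drop"
    )
  out <- dplyr::bind_rows(tbl, national)
  dplyr::bind_rows(out, annual_rows(out))
}

#' @export
print.ozone_assessment <- function(x, ...) {
  cat("<ozone_assessment>\n")
  print(x$table, n = Inf)
  invisible(x)
}

#' Tidy and glance methods for assessment results
#'
#' `tidy()` returns the full loss table; `glance()` the national annual
#' summary as one row.
#'
#' @param x An `ozone_assessment` from [run_assessment()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ozone_assessment
#' @export
tidy.ozone_assessment <- function(x, ...) x$table

#' @rdname tidy.ozone_assessment
#' @method glance ozone_assessment
#' @export
glance.ozone_assessment <- function(x, ...) {
  nat <- dplyr::filter(x$table, .data$sub_region == "National")
  tibble::tibble(
    production_t = nat$production_t[nat$season == "annual"],
    production_loss_t = nat$production_loss_t[nat$season == "annual"],
    mean_yield_loss_s1 = nat$mean_yield_loss_pct[nat$season == "season1"],
    mean_yield_loss_s2 = nat$mean_yield_loss_pct[nat$season == "season2"],
    slope = x$model$slope
  )
}

#' Published sub-regional bean production losses for Uganda, 2015
#'
#' Published reference estimates of per-sub-region seasonal production loss
#' (tonnes) for common beans in Uganda in 2015: one row per sub-region and
#' season, with the Karamoja sub-region assessed only in its single unimodal
#' season (its season-2 entry is missing). Useful for exercising
#' [aggregate_losses()] and as a magnitude benchmark for synthetic runs.
#' Values are printed (rounded-to-tonne) numbers, so column sums can differ
#' from independently printed totals by a tonne.
#'
#' @return Tibble with columns `sub_region`, `region`, `season`,
#'   `production_loss_t`.
#' @export
#' @examples
#' uganda_bean_losses() |> aggregate_losses() |>
#'   dplyr::filter(sub_region == "National")
uganda_bean_losses <- function() {
  rows <- tibble::tribble(
    ~sub_region,     ~region,    ~s1,     ~s2,
    "North Buganda", "Central",  10235,   5602,
    "South Buganda", "Central",  5662,    5365,
    "Bukedi",        "Eastern",  899,     604,
    "Busoga",        "Eastern",  6134,    1409,
    "Elgon",         "Eastern",  3785,    1705,
    "Teso",          "Eastern",  13,      6,
    "Acholi",        "Northern", 18496,   15556,
    "Lango",         "Northern", 20773,   7405,
    "West Nile",     "Northern", 5127,    9300,
    "Karamoja",      "Northern", 2338,    NA,
    "Ankole",        "Western",  19825,   11077,
    "Bunyoro",       "Western",  10722,   4385,
    "Kigezi",        "Western",  1853,    1835,
    "Tooro",         "Western",  8494,    5888
  )
  tidyr::pivot_longer(rows, c("s1", "s2"), names_to = "season",
                      values_to = "production_loss_t") |>
    dplyr::mutate(season = dplyr::recode(.data$season, s1 = "season1",
                                         s2 = "season2"))
}

#' Plot per-sub-region production losses
#'
#' @param tbl A loss table (e.g. `tidy()` of an assessment or
#'   [uganda_bean_losses()]).
#' @return A ggplot object: seasonal losses per sub-region.
#' @export
plot_loss_table <- function(tbl) {
  df <- dplyr::filter(tbl, .data$season %in% c("season1", "season2"),
                      .data$sub_region != "National")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$sub_region,
                                                      .data$production_loss_t),
                                   y = .data$production_loss_t,
                                   fill = .data$season)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "production loss (t)", fill = NULL)
}
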