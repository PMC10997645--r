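test_that("relative yield is 1 - loss/100 and rejects out-of-range input", {
  expect_equal(relative_yield(0), 1)
  expect_equal(relative_yield(20), 0.8)
  expect_equal(relative_yield(50), 0.5)
  expect_error(relative_yield(-1), "99.9")
  expect_error(relative_yield(100), "99.9")
})

test_that("production loss inflates observed production to the pre-loss potential", {
  expect_equal(production_loss(100, 0), 0)
  expect_equal(production_loss(100, 20), 25)
  expect_equal(production_loss(80, 50), 80)
  expect_equal(production_loss(0, 40), 0)
  expect_error(production_loss(-1, 10), "non-negative")
  # the literal reciprocal reading is exposed for audit and is visibly wrong
  expect_lt(production_loss(100, 20, literal = TRUE), 0)
})

test_that("loss fraction identity holds across a grid of inputs", {
  P <- c(0.5, 10, 100, 1e4)
  yl <- c(0.1, 5, 17.09, 27.5, 60, 99)
  for (p in P) for (y in yl) {
    loss <- production_loss(p, y)
    expect_equal(loss, p * y / (100 - y), tolerance = 1e-12)
    expect_equal(loss / (p + loss), y / 100, tolerance = 1e-12)
  }
})

make_assessment_fixture <- function(pod_a = 10 / 1.175, pod_b = 4,
                                    tonnes = 100, n = 4) {
  fx <- two_region_fixture(n)
  g <- fx$grid
  podm <- matrix(NA_real_, n, n)
  podm[fx$regions$assignment == "A"] <- pod_a
  podm[fx$regions$assignment == "B"] <- pod_b
  mk_pod <- function() {
    f <- raster_field(g, podm, units = "mmol m-2")
    class(f) <- c("pod_field", class(f))
    f
  }
  splits <- seasonal_split_table(c("A", "B"))
  pr <- production_raster(g, matrix(tonnes, n, n), year = 2015)
  seasonal <- split_seasons(pr, splits, fx$regions)
  list(fx = fx, pod = list(season1 = mk_pod(), season2 = mk_pod()),
       seasonal = seasonal)
}

test_that("uniform 10% yield loss on 1000 t in a season loses 111.1 t", {
  # dose chosen so the slope gives exactly 10% loss; each sub-region holds
  # 8 cells x 125 t = 1000 t annual production, split 60:40
  f <- make_assessment_fixture(pod_a = 10 / 1.175, pod_b = 10 / 1.175,
                               tonnes = 1000 / 8)
  a <- run_assessment(f$pod, default_flux_effect_model(), f$seasonal,
                      f$fx$regions)
  s1 <- dplyr::filter(a$table, sub_region == "A", season == "season1")
  expect_equal(s1$production_t, 600)
  expect_equal(s1$mean_yield_loss_pct, 10, tolerance = 1e-12)
  expect_equal(s1$production_loss_t, 600 * 10 / 90, tolerance = 1e-9)
  ann <- dplyr::filter(a$table, sub_region == "A", season == "annual")
  expect_equal(ann$production_loss_t, 1000 * 10 / 90, tolerance = 1e-9)
  expect_equal(1000 * 10 / 90, 111.1, tolerance = 1e-3)
  nat1 <- dplyr::filter(a$table, sub_region == "National", season == "season1")
  expect_equal(nat1$production_t, 1200)
  expect_equal(nat1$production_loss_t, 1200 * 10 / 90, tolerance = 1e-9)
})

test_that("zero dose everywhere gives zero loss everywhere", {
  f <- make_assessment_fixture(pod_a = 0, pod_b = 0)
  a <- run_assessment(f$pod, default_flux_effect_model(), f$seasonal,
                      f$fx$regions)
  expect_true(all(a$table$mean_yield_loss_pct[
    a$table$season != "annual"] == 0))
  expect_true(all(a$table$production_loss_t == 0))
})

test_that("a two-region fixture matches the closed-form per-region computation", {
  pod_a <- 8; pod_b <- 2; tonnes <- 50
  f <- make_assessment_fixture(pod_a = pod_a, pod_b = pod_b, tonnes = tonnes)
  a <- run_assessment(f$pod, default_flux_effect_model(), f$seasonal,
                      f$fx$regions)
  for (rg in c("A", "B")) {
    podv <- if (rg == "A") pod_a else pod_b
    yl <- 1.175 * podv
    for (s in c("season1", "season2")) {
      share <- if (s == "season1") 0.6 else 0.4
      p <- 8 * tonnes * share
      row <- dplyr::filter(a$table, sub_region == rg, season == s)
      expect_equal(row$mean_yield_loss_pct, yl, tolerance = 1e-12)
      expect_equal(row$production_t, p, tolerance = 1e-12)
      expect_equal(row$production_loss_t, p * yl / (100 - yl),
                   tolerance = 1e-12)
    }
  }
})

test_that("national loss equals the sum of sub-region losses and annual rows add up", {
  f <- make_assessment_fixture(pod_a = 12, pod_b = 3)
  a <- run_assessment(f$pod, default_flux_effect_model(), f$seasonal,
                      f$fx$regions)
  tbl <- a$table
  for (s in c("season1", "season2")) {
    nat <- dplyr::filter(tbl, sub_region == "National", season == s)
    subs <- dplyr::filter(tbl, sub_region != "National", season == s)
    expect_equal(nat$production_loss_t, sum(subs$production_loss_t),
                 tolerance = 1e-9)
  }
  ann <- dplyr::filter(tbl, season == "annual")
  for (r in unique(ann$sub_region)) {
    seasons <- dplyr::filter(tbl, sub_region == r, season != "annual")
    expect_equal(ann$production_loss_t[ann$sub_region == r],
                 sum(seasons$production_loss_t, na.rm = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("raising any cell's dose never decreases any aggregate loss", {
  f <- make_assessment_fixture(pod_a = 5, pod_b = 5)
  base <- run_assessment(f$pod, default_flux_effect_model(), f$seasonal,
                         f$fx$regions)$table
  bumped_pod <- f$pod
  bumped_pod$season1$values[2, 2] <- bumped_pod$season1$values[2, 2] + 3
  bumped <- run_assessment(bumped_pod, default_flux_effect_model(),
                           f$seasonal, f$fx$regions)$table
  expect_true(all(bumped$production_loss_t - base$production_loss_t >= -1e-12,
                  na.rm = TRUE))
})

test_that("unimodal sub-regions are assessed once, against their own window", {
  fx <- two_region_fixture(4)
  g <- fx$grid
  mk_pod <- function(v) {
    f <- raster_field(g, matrix(v, 4, 4), units = "mmol m-2")
    class(f) <- c("pod_field", class(f))
    f
  }
  splits <- seasonal_split_table(c("A", "B"), unimodal = "B")
  pr <- production_raster(g, matrix(100, 4, 4), year = 2015)
  seasonal <- split_seasons(pr, splits, fx$regions)
  pods <- list(season1 = mk_pod(10), season2 = mk_pod(10),
               unimodal = mk_pod(20))
  a <- run_assessment(pods, default_flux_effect_model(), seasonal,
                      fx$regions, unimodal_windows = c(B = "unimodal"))
  b1 <- dplyr::filter(a$table, sub_region == "B", season == "season1")
  expect_equal(b1$mean_yield_loss_pct, 1.175 * 20)  # unimodal window dose
  expect_equal(b1$production_t, 800)                # all of B's production
  b2 <- dplyr::filter(a$table, sub_region == "B", season == "season2")
  expect_true(is.na(b2$mean_yield_loss_pct))
  expect_true(is.na(b2$production_loss_t))
  ann <- dplyr::filter(a$table, sub_region == "B", season == "annual")
  expect_equal(ann$production_loss_t, b1$production_loss_t)
})

test_that("season label mismatches are rejected", {
  f <- make_assessment_fixture()
  swapped <- list(season1 = f$seasonal$season2, season2 = f$seasonal$season1)
  expect_error(run_assessment(f$pod, default_flux_effect_model(), swapped,
                              f$fx$regions), "labelled")
})

test_that("aggregating the published loss table reproduces its printed totals", {
  agg <- aggregate_losses(uganda_bean_losses())
  nat <- dplyr::filter(agg, sub_region == "National")
  expect_identical(nat$production_loss_t[nat$season == "season2"], 70137)
  expect_lte(abs(nat$production_loss_t[nat$season == "season1"] - 114355), 1)
  ann <- dplyr::filter(agg, season == "annual", sub_region != "National")
  want <- c("North Buganda" = 15837, "Acholi" = 34052, "Ankole" = 30902,
            "Karamoja" = 2338)
  got <- stats::setNames(ann$production_loss_t, ann$sub_region)[names(want)]
  expect_equal(got, want)
})
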