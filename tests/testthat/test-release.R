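site_fixture <- function() {
  tibble::tibble(site_id = 1L, lon = 10.2, lat = 57.2,
                 bed_depths = list(bed_depth_quota()))
}

test_that("default forward schedule realizes the printed release quotas", {
  ev <- schedule_releases(site_fixture(), spawning_config(), mode = "forward",
                          seed = 1)
  expect_equal(nrow(ev), 3000)
  # 75% in the first window (15 May - 14 Jul), exactly
  expect_equal(sum(ev$window == 1), 2250)
  expect_equal(sum(ev$window == 2), 750)
  # every hour of both windows has at least one release
  h1 <- 61 * 24; h2 <- 31 * 24
  counts <- table(factor(ev$time_h, levels = 0:(h1 + h2 - 1)))
  expect_true(all(counts >= 1))
  expect_equal(sum(counts), 3000)
  # no event outside the configured windows
  expect_true(all(ev$time_h >= 0 & ev$time_h < h1 + h2))
})

test_that("a tight window forces exactly one release per hour", {
  cfg <- spawning_config(
    forward_windows = tibble::tibble(start = 0, end = 10, fraction = 1),
    n_total = 10, min_per_hour = 1)
  ev <- schedule_releases(site_fixture(), cfg, "forward", seed = 1)
  expect_equal(sort(ev$time_h), 0:9)
})

test_that("infeasible min-per-hour demands are refused", {
  cfg <- spawning_config(
    forward_windows = tibble::tibble(start = 0, end = 100, fraction = 1),
    n_total = 50, min_per_hour = 1)
  expect_error(schedule_releases(site_fixture(), cfg, "forward"),
               "cannot satisfy min-per-hour")
})

test_that("the scheduler is deterministic and windows are exact across seeds", {
  s <- site_fixture()
  e1 <- schedule_releases(s, spawning_config(), "forward", seed = 3)
  e2 <- schedule_releases(s, spawning_config(), "forward", seed = 3)
  expect_identical(e1, e2)
  e3 <- schedule_releases(s, spawning_config(), "forward", seed = 4)
  # RNG affects only within-band depth values, not times or band counts
  expect_identical(e1$time_h, e3$time_h)
  expect_false(identical(e1$drift_depth_m, e3$drift_depth_m))
  bands1 <- table(cut(e1$drift_depth_m, c(0, 10, 20, 30), right = FALSE))
  bands3 <- table(cut(e3$drift_depth_m, c(0, 10, 20, 30), right = FALSE))
  expect_equal(as.vector(bands1), as.vector(bands3))
})

test_that("drift and bed depth quotas are exact", {
  d <- assign_depths(3000, depth_quota(), seed = 1)
  expect_equal(sum(d >= 0 & d < 10), 1200)
  expect_equal(sum(d >= 10 & d < 20), 1200)
  expect_equal(sum(d >= 20 & d < 30), 600)

  bq <- depth_quota(tibble::tibble(lower = c(0.5, 2, 4, 6),
                                   upper = c(0.5, 2, 4, 6),
                                   weight = c(0.7, 0.1, 0.1, 0.1)))
  bd <- assign_depths(10, bq, seed = 1)
  expect_equal(sum(bd == 0.5), 7)
  expect_equal(sort(unique(bd)), c(0.5, 2, 4, 6))

  one <- assign_depths(1, depth_quota(tibble::tibble(lower = 5, upper = 8,
                                                     weight = 1)), seed = 2)
  expect_true(one >= 5 && one < 8)
})

test_that("backward-mode releases sit at mussel-bed depths", {
  cfg <- spawning_config(
    backward_windows = tibble::tibble(start = 0, end = 100, fraction = 1),
    n_total = 100, min_per_hour = 1)
  ev <- schedule_releases(site_fixture(), cfg, "backward", seed = 1)
  expect_equal(nrow(ev), 100)
  expect_setequal(unique(ev$release_depth_m), c(0.5, 2, 4, 6))
  expect_equal(sum(ev$release_depth_m == 0.5), 70)
  # drift depths still follow the drift quota
  expect_equal(sum(ev$drift_depth_m < 10), 40)
})

test_that("the development model reproduces its fitted coefficients", {
  expect_equal(development_time(1), 101.32)
  expect_equal(development_time(exp(1)), 101.32 - 28.06)
  # independent high-precision evaluation at 15 degrees C
  expect_equal(development_time(15), -28.06 * log(15) + 101.32)
  expect_lt(abs(development_time(15) - 25.33), 0.01)
  expect_error(development_time(0), "temperature > 0")
  expect_error(development_time(-3), "temperature > 0")
})

test_that("site mean development time averages hourly model values", {
  b <- tiny_shelf()
  f <- still_field(b, duration_days = 3, time_step_hours = 72)
  f$temperature[] <- 15
  site <- list(lon = 10.2, lat = 57.2)
  expect_equal(site_mean_development_time(site, f, c(0, 48)),
               development_time(15))
  # two-hour window at 1 and e degrees: hand average of the two model values
  f2 <- still_field(b, duration_days = 1, time_step_hours = 1)
  f2$temperature[] <- 1
  f2$temperature[, , , 2] <- exp(1)
  got <- site_mean_development_time(site, f2, c(0, 1))
  expect_equal(got, mean(c(101.32, 73.26)), tolerance = 1e-6)
  expect_equal(round(got, 2), 87.29)
  expect_error(site_mean_development_time(site, f, c(0, 1000)),
               "window outside")
})
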