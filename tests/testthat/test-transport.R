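test_that("velocity sampling honours the interpolation contract", {
  b <- tiny_shelf()
  f <- uniform_field(b, u = 0.1, v = 0)
  got <- sample_velocity(f, c(10.2, 10.31, 10.05), c(57.2, 57.33, 57.44),
                         5, c(0, 10, 20))
  expect_equal(got$u, rep(0.1, 3))
  expect_equal(got$v, rep(0, 3))

  # identity at a stored cell centre and stored time
  f2 <- still_field(b)
  i <- 10; j <- 12
  f2$u[i, j, 1, ] <- 0.23
  got2 <- sample_velocity(f2, b$lon_centers[i], b$lat_centers[j], 5, 0)
  expect_equal(got2$u, 0.23)

  # hand bilinear value midway between two cell centres
  f3 <- still_field(b)
  f3$u[i + 1, j, 1, ] <- 0.2 # neighbour has 0.2, cell i has 0
  mid <- (b$lon_centers[i] + b$lon_centers[i + 1]) / 2
  got3 <- sample_velocity(f3, mid, b$lat_centers[j], 5, 0)
  expect_equal(got3$u, 0.1)

  expect_error(sample_velocity(f, 10.2, 57.2, 5, 1e6), "time axis")
})

test_that("uniform-flow displacement matches u*t to within 0.1%", {
  b <- tiny_shelf()
  f <- uniform_field(b, u = 0.1, v = 0)
  sch <- one_particle_schedule(10.05, 57.25)
  tr <- advect(sch, f, tracker_config(horizontal_diffusivity = 0),
               horizon_days = 1)
  end <- c(tr$lon[1, ncol(tr$lon)], tr$lat[1, ncol(tr$lat)])
  d_m <- (end[1] - 10.05) * 111194.9 * cos(57.25 * pi / 180)
  skip_if_not_installed("geosphere")
  d_gc <- geosphere::distHaversine(c(10.05, 57.25), end, r = 6371008.8)
  expect_lt(abs(d_m - 8640) / 8640, 0.001)
  expect_lt(abs(d_gc - 8640) / 8640, 0.001)
  expect_equal(end[2], 57.25)
})

test_that("a still ocean leaves particles exactly in place", {
  b <- tiny_shelf()
  f <- still_field(b)
  sch <- one_particle_schedule(10.22, 57.31)
  tr <- advect(sch, f, tracker_config(horizontal_diffusivity = 0),
               horizon_days = 1)
  expect_true(all(tr$lon[1, ] == 10.22))
  expect_true(all(tr$lat[1, ] == 57.31))
})

test_that("backward tracing inverts forward drift in steady flow", {
  b <- tiny_shelf()
  f <- make_flow_field(b, duration_days = 60, time_step_hours = 60 * 24,
                       gyre_strength = 0.03, jet_speed = 0.01,
                       depth_levels = 5)
  sch <- one_particle_schedule(10.1, 57.25)
  fw <- advect(sch, f, tracker_config(horizontal_diffusivity = 0),
               horizon_days = 27)
  q <- c(fw$lon[1, ncol(fw$lon)], fw$lat[1, ncol(fw$lat)])
  bw <- advect(one_particle_schedule(q[1], q[2], time_h = 27 * 24,
                                     mode = "backward"),
               f, tracker_config(horizontal_diffusivity = 0),
               mode = "backward", horizon_days = 27)
  r <- c(bw$lon[1, ncol(bw$lon)], bw$lat[1, ncol(bw$lat)])
  path <- sqrt(sum((q - c(10.1, 57.25))^2))
  expect_gt(path, 0.05) # the particle actually moved
  expect_lt(sqrt(sum((r - c(10.1, 57.25))^2)), 1e-3 * path)
  # backward trajectories run on a decreasing field-time axis
  expect_true(all(diff(bw$times_h) < 0))
})

test_that("zero-diffusion trajectories are seed-independent", {
  b <- tiny_shelf()
  f <- make_flow_field(b, duration_days = 3, time_step_hours = 72,
                       gyre_strength = 0.03, depth_levels = 5)
  sch <- one_particle_schedule(10.1, 57.25)
  t1 <- advect(sch, f, tracker_config(horizontal_diffusivity = 0, seed = 1),
               horizon_days = 2)
  t2 <- advect(sch, f, tracker_config(horizontal_diffusivity = 0, seed = 99),
               horizon_days = 2)
  expect_identical(t1$lon, t2$lon)
})

test_that("diffusion reproduces its displacement statistics", {
  b <- tiny_shelf()
  f <- still_field(b)
  kh <- 1
  n <- 1000
  sch <- one_particle_schedule(rep(10.25, n), rep(57.25, n))
  t_days <- 1
  tr <- advect(sch, f, tracker_config(horizontal_diffusivity = kh, seed = 2),
               horizon_days = t_days)
  dx_m <- (tr$lon[, ncol(tr$lon)] - 10.25) * 111194.9 * cos(57.25 * pi / 180)
  dy_m <- (tr$lat[, ncol(tr$lat)] - 57.25) * 111194.9
  v_theory <- 2 * kh * t_days * 86400
  # variance of the sample variance: ~ 2 sigma^4 / (n - 1)
  se_var <- sqrt(2 / (n - 1)) * v_theory
  expect_lt(abs(var(dx_m) - v_theory), 3 * se_var)
  expect_lt(abs(var(dy_m) - v_theory), 3 * se_var)
  se_mean <- sqrt(v_theory / n)
  expect_lt(abs(mean(dx_m)), 3 * se_mean)
  expect_lt(abs(mean(dy_m)), 3 * se_mean)
})

test_that("particles never sit on land under reflective coast handling", {
  b <- make_coastal_bathymetry(seed = 1)
  f <- make_flow_field(b, duration_days = 6, time_step_hours = 6 * 24,
                       gyre_strength = 0.02, jet_speed = 0.03,
                       jet_width = 5000, depth_levels = 5)
  s <- place_sites(b, 8, seed = 3)
  sch <- schedule_all_releases(
    s, spawning_config(forward_windows = tibble::tibble(start = 0, end = 24,
                                                        fraction = 1),
                       n_total = 30, min_per_hour = 1),
    mode = "forward", seed = 1)
  tr <- advect(sch, f, tracker_config(horizontal_diffusivity = 20, seed = 4),
               horizon_days = 5)
  for (p in seq_len(nrow(tr$lon))) {
    ok <- !is.na(tr$lon[p, ])
    expect_true(all(is_water(b, tr$lon[p, ok], tr$lat[p, ok])))
  }
  expect_true(all(tr$meta$status %in% c("drifting", "lost_domain")))
})

test_that("particles crossing the open boundary are flagged and frozen", {
  b <- tiny_shelf()
  f <- uniform_field(b, u = 0.5, v = 0) # fast: exits the 0.5-degree box
  sch <- one_particle_schedule(10.45, 57.25)
  tr <- advect(sch, f, tracker_config(horizontal_diffusivity = 0),
               horizon_days = 1)
  expect_equal(tr$meta$status, "lost_domain")
  last <- tr$lon[1, ncol(tr$lon)]
  expect_true(last <= max(b$lon_edges))
  # frozen: last two stored positions identical
  expect_equal(tr$lon[1, ncol(tr$lon)], tr$lon[1, ncol(tr$lon) - 1])
})

test_that("insufficient field duration is reported with the shortfall", {
  b <- tiny_shelf()
  f <- still_field(b, duration_days = 2)
  expect_error(advect(one_particle_schedule(10.2, 57.2), f,
                      tracker_config(), horizon_days = 33),
               "shortfall")
})

test_that("positions_during returns dwell-weighted sub-tracks", {
  b <- tiny_shelf()
  f <- still_field(b, duration_days = 7, time_step_hours = 7 * 24)
  sch <- one_particle_schedule(10.2, 57.2)
  tr <- advect(sch, f, tracker_config(horizontal_diffusivity = 0),
               horizon_days = 6)
  full <- positions_during(tr, 0, 6)
  expect_equal(sum(full$dwell_h), 6 * 24)
  expect_equal(nrow(positions_during(tr, 2, 2)), 0)
  # stationary particle: all samples at the release point
  win <- positions_during(tr, 0, 6)
  expect_true(all(win$lon == 10.2 & win$lat == 57.2))
  expect_error(positions_during(tr, 2, 40), "outside")
})
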