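# Small shared fixtures, built in code at test time.

# An open 0.5 x 0.5 degree shelf (no land) with a single depth level.
tiny_shelf <- function(step = 0.015) {
  make_coastal_bathymetry(c(10, 10.5), c(57, 57.5), step = step,
                          land_frame = 0, islands = 0, fjords = list(),
                          seed = 1)
}

# A still flow field over a bathymetry; velocities can be overwritten.
still_field <- function(bathy, duration_days = 2, depth_levels = 5,
                        time_step_hours = duration_days * 24) {
  make_flow_field(bathy, duration_days = duration_days,
                  time_step_hours = time_step_hours, gyre_strength = 0,
                  jet_speed = 0, noise_amplitude = 0,
                  depth_levels = depth_levels)
}

# Uniform-velocity field (m/s).
uniform_field <- function(bathy, u = 0.1, v = 0, duration_days = 2,
                          depth_levels = 5) {
  f <- still_field(bathy, duration_days, depth_levels)
  f$u[] <- u
  f$v[] <- v
  f
}

one_particle_schedule <- function(lon, lat, time_h = 0, depth = 5,
                                  mode = "forward", site_id = 1L) {
  tibble::tibble(site_id = site_id, mode = mode, time_h = time_h,
                 lon = lon, lat = lat, release_depth_m = depth,
                 drift_depth_m = depth)
}

# A synthetic trajectory that sits in given cells of a bathymetry for given
# numbers of samples during the competency window (and over deep water for
# the remainder). `cells` is a list of c(ix, iy); `n_samples` per cell.
dwell_trajectory <- function(bathy, cells, n_samples, deep_cell,
                             window_days = c(27, 33), step_h = 0.6) {
  w0 <- window_days[1] * 24; w1 <- window_days[2] * 24
  times <- seq(w0, w1 - step_h, by = step_h)
  total <- length(times)
  stopifnot(sum(n_samples) <= total)
  seg <- rep(length(cells) + 1L, total)
  pos <- 1L
  for (i in seq_along(cells)) {
    seg[pos:(pos + n_samples[i] - 1L)] <- i
    pos <- pos + n_samples[i]
  }
  all_cells <- c(cells, list(deep_cell))
  lon <- vapply(seg, function(s) bathy$lon_centers[all_cells[[s]][1]], 1)
  lat <- vapply(seg, function(s) bathy$lat_centers[all_cells[[s]][2]], 1)
  trajectory_set(times, matrix(lon, 1), matrix(lat, 1), release_time_h = 0,
                 output_step_h = step_h,
                 horizon_days = window_days[2])
}

# Flood-fill reachability oracle on a water mask: which cells are reachable
# from a starting cell by 4-neighbour moves over water? Independent of the
# package's component labelling.
flood_reachable <- function(water, start) {
  nx <- nrow(water); ny <- ncol(water)
  seen <- matrix(FALSE, nx, ny)
  stack <- list(start)
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- cur[1]; j <- cur[2]
    if (i < 1 || i > nx || j < 1 || j > ny) next
    if (seen[i, j] || !water[i, j]) next
    seen[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
  }
  seen
}
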