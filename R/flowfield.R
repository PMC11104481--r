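#' Generate a synthetic coastal flow and temperature field
#'
#' Builds hourly-to-steady gridded currents over a [make_coastal_bathymetry()]
#' domain. The deterministic part of the flow is derived from a streamfunction
#' (so its central-difference divergence is zero by construction): a basin-scale
#' counterclockwise gyre plus a coastline-following jet that decays offshore
#' with an e-folding width `jet_width`. Optional streamfunction noise adds
#' time-varying, still divergence-free, eddies. Velocities are zero on land.
#' Temperature is a seasonal sinusoid attenuated with depth, spatially uniform
#' over water (it only feeds larval-development diagnostics).
#'
#' Currents are identical across depth levels (depth bands select a level but
#' the synthetic circulation is barotropic); fjord interiors are sheltered from
#' the open-coast circulation by the multiplicative factor `fjord_shelter`.
#'
#' @param bathy A `bathy_grid`.
#' @param duration_days Length of the field, days.
#' @param time_step_hours Time step of the stored slices, hours. Use a large
#'   value (up to `duration_days * 24`) for a steady field; the tracker
#'   interpolates linearly in time.
#' @param gyre_strength Approximate peak gyre speed, m/s. Positive values give
#'   a counterclockwise (cyclonic) basin gyre.
#' @param jet_speed Peak speed of the coast-following jet at the shore, m/s,
#'   counterclockwise sense.
#' @param jet_width Offshore e-folding width of the jet, metres.
#' @param noise_amplitude Standard deviation of per-cell streamfunction noise
#'   expressed as an equivalent speed, m/s. 0 disables noise.
#' @param fjord_shelter Velocity multiplier applied inside carved fjords
#'   (0 = quiescent, 1 = unsheltered).
#' @param fjord_outflow Net seaward residual speed prescribed in fjord strait
#'   cells, m/s, representing estuarine exchange through the mouth. This
#'   component is prescribed directly (not streamfunction-derived), so the
#'   discrete divergence identity holds only away from strait junctions.
#' @param depth_levels Depth levels, metres (defaults match the larval drift
#'   depth bands: 5, 15, 25).
#' @param temp_mean,temp_amplitude Seasonal surface temperature mean and
#'   amplitude, degrees C.
#' @param temp_peak_doy Day-of-year of the temperature maximum.
#' @param temp_depth_scale Depth attenuation scale of the seasonal signal, m.
#' @param start_date Calendar date of field time zero.
#' @param seed Seed for the noise field (ignored when `noise_amplitude = 0`).
#' @return An object of class `flow_field`: times (`times_h`, hours since
#'   `start_date`), `depth_levels`, arrays `u`, `v`, `temperature` with
#'   dimensions (lon, lat, depth, time), and the `bathy` grid.
#' @export
make_flow_field <- function(bathy, duration_days = 60, time_step_hours = 1,
                            gyre_strength = 0.05, jet_speed = 0,
                            jet_width = 10000, noise_amplitude = 0,
                            fjord_shelter = 0.1, fjord_outflow = 0.01,
                            depth_levels = c(5, 15, 25),
                            temp_mean = 14, temp_amplitude = 5,
                            temp_peak_doy = 220, temp_depth_scale = 25,
                            start_date = as.Date("2017-05-01"), seed = NULL) {
  stopifnot(duration_days > 0, time_step_hours > 0)
  lon_c <- bathy$lon_centers; lat_c <- bathy$lat_centers
  nx <- length(lon_c); ny <- length(lat_c)
  times_h <- seq(0, duration_days * 24, by = time_step_hours)
  if (tail(times_h, 1) < duration_days * 24)
    times_h <- c(times_h, duration_days * 24)
  nt <- length(times_h)

  lat_mid <- mean(range(lat_c))
  Lx <- diff(range(bathy$lon_edges)) * m_per_deg_lon(lat_mid)
  Ly <- diff(range(bathy$lat_edges)) * m_per_deg_lat()
  xhat <- (lon_c - bathy$lon_edges[1]) / diff(range(bathy$lon_edges))
  yhat <- (lat_c - bathy$lat_edges[1]) / diff(range(bathy$lat_edges))

  # Streamfunction on cell centers (m^2/s). Negative sin-sin bowl =>
  # counterclockwise circulation (positive relative vorticity).
  amp_g <- gyre_strength * min(Lx, Ly) / pi
  psi_gyre <- -amp_g * outer(sin(pi * xhat), sin(pi * yhat))
  cell_m <- (bathy$step * (m_per_deg_lon(lat_mid) + m_per_deg_lat()) / 2)
  d_m <- bathy$dist_land * cell_m
  psi_jet <- -jet_speed * jet_width * (1 - exp(-d_m / jet_width))
  psi0 <- psi_gyre + psi_jet

  dx_m <- bathy$step * m_per_deg_lon(lat_c) # per latitude row
  dy_m <- bathy$step * m_per_deg_lat()
  shelter <- matrix(1, nx, ny)
  if (nrow(bathy$fjords) > 0) {
    grid_lon <- matrix(lon_c, nx, ny)
    grid_lat <- matrix(lat_c, nx, ny, byrow = TRUE)
    shelter[in_fjord(bathy, as.vector(grid_lon), as.vector(grid_lat))] <- fjord_shelter
  }

  uv_from_psi <- function(psi) {
    # Central differences; one-sided at edges (edge cells are land anyway
    # whenever a land frame exists).
    iL <- c(1, seq_len(nx - 1)); iR <- c(seq_len(nx - 1) + 1, nx)
    jD <- c(1, seq_len(ny - 1)); jU <- c(seq_len(ny - 1) + 1, ny)
    ddx <- matrix(rep((iR - iL), ny), nx, ny)
    ddy <- matrix(rep((jU - jD), each = nx), nx, ny)
    u <- -(psi[, jU] - psi[, jD]) / (ddy * dy_m)
    v <- (psi[iR, ] - psi[iL, ]) / (ddx *
      matrix(rep(dx_m, each = nx), nx, ny))
    u <- u * shelter; v <- v * shelter
    if (fjord_outflow > 0 && nrow(bathy$fjords) > 0) {
      for (k in seq_len(nrow(bathy$fjords))) {
        fj <- bathy$fjords[k, ]
        ix <- which(lon_c > fj$lon_min & lon_c < fj$lon_max)
        iy <- which(lat_c > fj$lat_min & lat_c < fj$lat_max)
        bx <- which(lon_c > fj$basin_lon_min & lon_c < fj$basin_lon_max)
        by <- which(lat_c > fj$basin_lat_min & lat_c < fj$basin_lat_max)
        for (i in ix) for (j in iy) {
          if ((i %in% bx && j %in% by) || bathy$land_mask[i, j]) next
          if (fj$side == "E") u[i, j] <- -fjord_outflow
          if (fj$side == "W") u[i, j] <- fjord_outflow
          if (fj$side == "N") v[i, j] <- -fjord_outflow
          if (fj$side == "S") v[i, j] <- fjord_outflow
        }
      }
    }
    u[bathy$land_mask] <- 0; v[bathy$land_mask] <- 0
    list(u = u, v = v)
  }

  nz <- length(depth_levels)
  u <- array(0, c(nx, ny, nz, nt))
  v <- array(0, c(nx, ny, nz, nt))
  base <- uv_from_psi(psi0)
  noise_sd <- noise_amplitude * cell_m
  slices <- with_seed(seed, lapply(seq_len(nt), function(it) {
    if (noise_amplitude > 0) {
      uv_from_psi(psi0 + matrix(rnorm(nx * ny, sd = noise_sd), nx, ny))
    } else base
  }))
  for (it in seq_len(nt)) for (iz in seq_len(nz)) {
    u[, , iz, it] <- slices[[it]]$u
    v[, , iz, it] <- slices[[it]]$v
  }

  doy <- as.numeric(start_date - as.Date(format(start_date, "%Y-01-01"))) + 1 +
    times_h / 24
  t_season <- temp_mean + temp_amplitude *
    cos(2 * pi * (doy - temp_peak_doy) / 365.25)
  atten <- exp(-depth_levels / temp_depth_scale)
  temperature <- array(NA_real_, c(nx, ny, nz, nt))
  water <- !bathy$land_mask
  for (it in seq_len(nt)) for (iz in seq_len(nz)) {
    slice <- matrix(NA_real_, nx, ny)
    slice[water] <- temp_mean + (t_season[it] - temp_mean) * atten[iz]
    temperature[, , iz, it] <- slice
  }

  structure(list(times_h = times_h, depth_levels = depth_levels,
                 u = u, v = v, temperature = temperature,
                 start_date = start_date, bathy = bathy),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> ", dim(x$u)[1], "x", dim(x$u)[2], " cells, ",
      length(x$depth_levels), " depth level(s), ", length(x$times_h),
      " time slice(s) over ", round(tail(x$times_h, 1) / 24, 1), " days\n",
      sep = "")
  invisible(x)
}

# Nearest depth level index (ties resolved to the shallower level).
depth_level_index <- function(field, depth) {
  dl <- field$depth_levels
  vapply(depth, function(d) which.min(abs(dl - d))[1], integer(1))
}

# Internal vectorized sampler for one 4-D array. Bilinear in lon/lat among
# water cells (land cells dropped from the stencil, weights renormalized),
# nearest depth level, linear in time. Returns NA where the full stencil is
# land or the point is outside the grid.
.sample_array <- function(arr, field, lon, lat, kz, t_h) {
  b <- field$bathy
  lon_c <- b$lon_centers; lat_c <- b$lat_centers
  nx <- length(lon_c); ny <- length(lat_c)
  n <- length(lon)

  ix <- pmin(pmax(findInterval(lon, lon_c), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(lat, lat_c), 1L), ny - 1L)
  wx <- pmin(pmax((lon - lon_c[ix]) / (lon_c[ix + 1L] - lon_c[ix]), 0), 1)
  wy <- pmin(pmax((lat - lat_c[iy]) / (lat_c[iy + 1L] - lat_c[iy]), 0), 1)

  tv <- field$times_h
  it <- pmin(pmax(findInterval(t_h, tv), 1L), length(tv) - 1L)
  wt <- (t_h - tv[it]) / (tv[it + 1L] - tv[it])
  wt <- pmin(pmax(wt, 0), 1)

  corner <- function(dx, dy) {
    ci <- ix + dx; cj <- iy + dy
    w <- (if (dx == 0) 1 - wx else wx) * (if (dy == 0) 1 - wy else wy)
    water <- !b$land_mask[cbind(ci, cj)]
    f0 <- arr[cbind(ci, cj, kz, it)]
    f1 <- arr[cbind(ci, cj, kz, it + 1L)]
    list(w = w * water, f = (1 - wt) * f0 + wt * f1)
  }
  acc_w <- numeric(n); acc_f <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) {
    cn <- corner(dx, dy)
    f <- cn$f; f[cn$w == 0] <- 0
    acc_w <- acc_w + cn$w
    acc_f <- acc_f + cn$w * f
  }
  out <- acc_f / acc_w
  out[acc_w == 0] <- NA_real_
  out
}

#' Sample velocity from a flow field
#'
#' Bilinear interpolation in lon/lat among water cells (land cells are excluded
#' from the stencil and the weights renormalized), nearest depth level, linear
#' interpolation in time. All arguments are vectorized.
#'
#' @param field A [make_flow_field()] object.
#' @param lon,lat Positions, degrees.
#' @param depth Sampling depth, metres (snapped to the nearest level).
#' @param t_h Time, hours since field start.
#' @return A tibble with columns `u` and `v` (m/s).
#' @export
sample_velocity <- function(field, lon, lat, depth, t_h) {
  n <- max(length(lon), length(lat), length(depth), length(t_h))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  depth <- rep_len(depth, n); t_h <- rep_len(t_h, n)
  if (any(t_h < field$times_h[1] - 1e-9 |
            t_h > tail(field$times_h, 1) + 1e-9))
    stop_lc("sample time outside the field's time axis")
  if (!all(is_water(field$bathy, lon, lat)))
    stop_lc("sample position on land or outside the domain")
  kz <- depth_level_index(field, depth)
  tibble::tibble(
    u = .sample_array(field$u, field, lon, lat, kz, t_h),
    v = .sample_array(field$v, field, lon, lat, kz, t_h)
  )
}

#' Sample temperature from a flow field
#'
#' Same interpolation contract as [sample_velocity()].
#'
#' @inheritParams sample_velocity
#' @return Numeric vector of temperatures, degrees C.
#' @export
sample_temperature <- function(field, lon, lat, depth, t_h) {
  n <- max(length(lon), length(lat), length(depth), length(t_h))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  depth <- rep_len(depth, n); t_h <- rep_len(t_h, n)
  if (any(t_h < field$times_h[1] - 1e-9 |
            t_h > tail(field$times_h, 1) + 1e-9))
    stop_lc("sample time outside the field's time axis")
  if (!all(is_water(field$bathy, lon, lat)))
    stop_lc("sample position on land or outside the domain")
  kz <- depth_level_index(field, depth)
  .sample_array(field$temperature, field, lon, lat, kz, t_h)
}
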