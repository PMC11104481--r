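#' Tracker configuration
#'
#' @param time_step_min Internal integration step, minutes.
#' @param horizontal_diffusivity Horizontal eddy diffusivity Kh, m^2/s.
#'   Per-step Gaussian displacements with standard deviation
#'   `sqrt(2 * Kh * dt)` are added independently on each horizontal axis.
#' @param scheme Integration scheme, `"rk4"` (default) or `"euler"`.
#' @param coast Coastline handling: `"reflect"` (specular reflection off the
#'   land-cell face, default) or `"halt"` (particle freezes, flagged
#'   `halted`).
#' @param seed Integer seed for the diffusion noise.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(time_step_min = 30, horizontal_diffusivity = 1,
                           scheme = c("rk4", "euler"),
                           coast = c("reflect", "halt"), seed = 1) {
  stopifnot(time_step_min > 0, horizontal_diffusivity >= 0)
  structure(list(time_step_min = time_step_min,
                 horizontal_diffusivity = horizontal_diffusivity,
                 scheme = match.arg(scheme), coast = match.arg(coast),
                 seed = seed), class = "tracker_config")
}

#' Construct a trajectory set from raw position histories
#'
#' Low-level constructor, mainly useful for building synthetic trajectories
#' when testing settlement scoring. `lon` and `lat` are particles x times
#' matrices on a shared time axis; `NA` marks samples before a particle's
#' release.
#'
#' @param times_h Shared time axis, hours since field start, in traversal
#'   order (decreasing for backward mode).
#' @param lon,lat Position matrices (particles x length(times_h)), degrees.
#' @param release_time_h Per-particle release time, hours.
#' @param mode `"forward"` or `"backward"`.
#' @param site_id Per-particle origin site (recycled).
#' @param status Per-particle status: `"drifting"`, `"lost_domain"` or
#'   `"halted"` (recycled).
#' @param output_step_h Spacing of the time axis, hours.
#' @param horizon_days Trajectory span per particle, days; inferred from the
#'   time axis and release times when omitted.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(times_h, lon, lat, release_time_h, mode = "forward",
                           site_id = 1L, status = "drifting",
                           output_step_h = NULL, horizon_days = NULL) {
  lon <- rbind(lon); lat <- rbind(lat)
  stopifnot(ncol(lon) == length(times_h), identical(dim(lon), dim(lat)))
  n <- nrow(lon)
  if (is.null(output_step_h))
    output_step_h <- if (length(times_h) > 1) abs(diff(times_h[1:2])) else 1
  meta <- tibble::tibble(
    particle = seq_len(n),
    site_id = rep_len(site_id, n),
    release_time_h = rep_len(release_time_h, n),
    status = rep_len(status, n)
  )
  if (is.null(horizon_days)) {
    sgn <- if (mode == "forward") 1 else -1
    horizon_days <- max(sgn * (outer(times_h, meta$release_time_h, `-`))) / 24 +
      output_step_h / 24
  }
  structure(list(times_h = times_h, lon = lon, lat = lat, meta = meta,
                 mode = mode, output_step_h = output_step_h,
                 horizon_days = horizon_days),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", nrow(x$lon), " particles x ", length(x$times_h),
      " output times (", x$mode, "); status: ",
      paste(names(table(x$meta$status)), table(x$meta$status),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# One deterministic derivative evaluation: degrees/hour at (lon, lat, t).
# Returns NA rows where the interpolation stencil is all land (treated as a
# coast hit by the caller).
.deriv_deg_h <- function(field, lon, lat, kz, t_h, sgn) {
  u <- .sample_array(field$u, field, lon, lat, kz, t_h)
  v <- .sample_array(field$v, field, lon, lat, kz, t_h)
  list(dlon = sgn * u * 3600 / m_per_deg_lon(lat),
       dlat = sgn * v * 3600 / m_per_deg_lat())
}

#' Advect a release schedule through a flow field
#'
#' Integrates passive particles at their fixed drift depth, forward or
#' backward in time. Backward mode steps the field clock in reverse (the exact
#' adjoint of the deterministic part); diffusion remains a forward random
#' walk in both modes. Particles crossing the open boundary are flagged
#' `lost_domain` and frozen; particles hitting the coast are reflected or
#' halted per the tracker configuration. Output positions are stored at
#' `output_step_h` regardless of the internal step.
#'
#' @param schedule A [schedule_releases()] /[schedule_all_releases()] tibble.
#' @param field A [make_flow_field()] object covering
#'   `[min release, max release + horizon]` (forward) or
#'   `[min release - horizon, max release]` (backward).
#' @param config A [tracker_config()].
#' @param mode `"forward"` or `"backward"`; defaults to the schedule's mode.
#' @param horizon_days Drift duration per particle, days. The default 33 spans
#'   the full competency window.
#' @param output_step_h Output sampling interval, hours.
#' @return A `trajectory_set`; `meta` carries the schedule columns plus final
#'   `status`.
#' @export
advect <- function(schedule, field, config = tracker_config(), mode = NULL,
                   horizon_days = 33, output_step_h = 1) {
  if (is.null(mode)) mode <- schedule$mode[[1]]
  mode <- match.arg(mode, c("forward", "backward"))
  sgn <- if (mode == "forward") 1 else -1
  b <- field$bathy
  n <- nrow(schedule)
  horizon_h <- horizon_days * 24
  rel <- schedule$time_h

  t_lo <- if (mode == "forward") min(rel) else min(rel) - horizon_h
  t_hi <- if (mode == "forward") max(rel) + horizon_h else max(rel)
  if (t_lo < field$times_h[1] - 1e-9 || t_hi > tail(field$times_h, 1) + 1e-9)
    stop_lc("field does not cover the drift horizon: need [", t_lo, ", ",
            t_hi, "] h but field spans [", field$times_h[1], ", ",
            tail(field$times_h, 1), "] h (shortfall ",
            round(max(field$times_h[1] - t_lo,
                      t_hi - tail(field$times_h, 1), 0), 2), " h)")
  if (!all(is_water(b, schedule$lon, schedule$lat)))
    stop_lc("release positions must lie on water")

  t_start <- if (mode == "forward") min(rel) else max(rel)
  times_out <- t_start + sgn * seq(0, (if (mode == "forward") t_hi - t_lo else
    t_hi - t_lo), by = output_step_h)
  nt <- length(times_out)
  lon_m <- matrix(NA_real_, n, nt)
  lat_m <- matrix(NA_real_, n, nt)

  lon <- schedule$lon; lat <- schedule$lat
  status <- rep("drifting", n)
  end_t <- rel + sgn * horizon_h
  kz <- depth_level_index(field, schedule$drift_depth_m)

  dt_h <- config$time_step_min / 60
  nsub <- max(1L, round(output_step_h / dt_h))
  dt_h <- output_step_h / nsub
  dt_s <- dt_h * 3600
  diff_sd_m <- sqrt(2 * config$horizontal_diffusivity * dt_s)

  # Record initial positions at each particle's release time.
  rel_idx <- round(abs(rel - t_start) / output_step_h) + 1L
  lon_m[cbind(seq_len(n), rel_idx)] <- lon
  lat_m[cbind(seq_len(n), rel_idx)] <- lat

  lon_edges <- b$lon_edges; lat_edges <- b$lat_edges

  reflect_one <- function(lo_old, la_old, lo_new, la_new) {
    # Specular reflection off the crossed cell face(s); if no reflected
    # candidate lands on water the particle stays put for this substep.
    io <- bin_index(lo_old, lon_edges); jo <- bin_index(la_old, lat_edges)
    i1 <- bin_index(lo_new, lon_edges); j1 <- bin_index(la_new, lat_edges)
    rl <- lo_new; rla <- la_new
    if (!is.na(i1) && !is.na(io) && i1 != io) {
      e <- if (i1 > io) lon_edges[io + 1L] else lon_edges[io]
      rl <- 2 * e - lo_new
    }
    if (!is.na(j1) && !is.na(jo) && j1 != jo) {
      e <- if (j1 > jo) lat_edges[jo + 1L] else lat_edges[jo]
      rla <- 2 * e - la_new
    }
    cands <- list(c(rl, la_new), c(lo_new, rla), c(rl, rla))
    for (cc in cands) {
      if (is_water(b, cc[1], cc[2])) return(cc)
    }
    c(lo_old, la_old)
  }

  with_seed(config$seed, {
    for (it in seq_len(nt - 1L)) {
      t_now <- times_out[it]
      for (ss in seq_len(nsub)) {
        tcur <- t_now + sgn * (ss - 1) * dt_h
        active <- which(status == "drifting" &
                          sgn * (tcur - rel) >= -1e-9 &
                          sgn * (end_t - tcur) > 1e-9)
        if (length(active) > 0) {
          lo <- lon[active]; la <- lat[active]; kk <- kz[active]
          k1 <- .deriv_deg_h(field, lo, la, kk, tcur, sgn)
          if (config$scheme == "rk4") {
            mid_t <- tcur + sgn * dt_h / 2
            k2 <- .deriv_deg_h(field, lo + k1$dlon * dt_h / 2,
                               la + k1$dlat * dt_h / 2, kk, mid_t, sgn)
            k3 <- .deriv_deg_h(field, lo + k2$dlon * dt_h / 2,
                               la + k2$dlat * dt_h / 2, kk, mid_t, sgn)
            k4 <- .deriv_deg_h(field, lo + k3$dlon * dt_h,
                               la + k3$dlat * dt_h, kk, tcur + sgn * dt_h, sgn)
            dlon <- (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon) / 6
            dlat <- (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat) / 6
            # Stages that strayed onto land/outside: fall back to Euler.
            bad <- !is.finite(dlon) | !is.finite(dlat)
            dlon[bad] <- k1$dlon[bad]; dlat[bad] <- k1$dlat[bad]
          } else {
            dlon <- k1$dlon; dlat <- k1$dlat
          }
          bad <- !is.finite(dlon) | !is.finite(dlat)
          dlon[bad] <- 0; dlat[bad] <- 0
          new_lo <- lo + dlon * dt_h
          new_la <- la + dlat * dt_h
          if (diff_sd_m > 0) {
            new_lo <- new_lo + rnorm(length(active), sd = diff_sd_m) /
              m_per_deg_lon(la)
            new_la <- new_la + rnorm(length(active), sd = diff_sd_m) /
              m_per_deg_lat()
          }
          # Open-boundary loss.
          outside <- new_lo < lon_edges[1] | new_lo >= tail(lon_edges, 1) |
            new_la < lat_edges[1] | new_la >= tail(lat_edges, 1)
          if (any(outside)) {
            status[active[outside]] <- "lost_domain"
            new_lo[outside] <- lo[outside]; new_la[outside] <- la[outside]
          }
          # Coast handling.
          onland <- !outside & !is_water(b, new_lo, new_la)
          if (any(onland)) {
            if (config$coast == "halt") {
              status[active[onland]] <- "halted"
              new_lo[onland] <- lo[onland]; new_la[onland] <- la[onland]
            } else {
              for (w in which(onland)) {
                p <- reflect_one(lo[w], la[w], new_lo[w], new_la[w])
                new_lo[w] <- p[1]; new_la[w] <- p[2]
              }
            }
          }
          lon[active] <- new_lo; lat[active] <- new_la
        }
      }
      t_next <- times_out[it + 1L]
      live <- sgn * (t_next - rel) >= -1e-9
      lon_m[live, it + 1L] <- lon[live]
      lat_m[live, it + 1L] <- lat[live]
    }
  })

  meta <- dplyr::mutate(tibble::as_tibble(schedule),
                        particle = dplyr::row_number(),
                        status = status,
                        release_time_h = .data$time_h)
  structure(list(times_h = times_out, lon = lon_m, lat = lat_m, meta = meta,
                 mode = mode, output_step_h = output_step_h,
                 horizon_days = horizon_days),
            class = "trajectory_set")
}

#' Extract the sub-track within an elapsed-time window
#'
#' Returns per-sample positions with dwell durations for the part of each
#' trajectory whose elapsed drift time falls in `[t_start_days, t_end_days)`
#' (half-open sample intervals of one output step). Sample times are measured
#' from each particle's own release, in the direction of tracing.
#'
#' @param traj A `trajectory_set`.
#' @param t_start_days,t_end_days Window bounds, days since release.
#' @return A tibble: `particle`, `site_id`, `status`, `time_h`, `elapsed_h`,
#'   `lon`, `lat`, `dwell_h`.
#' @export
positions_during <- function(traj, t_start_days, t_end_days) {
  stopifnot(t_end_days >= t_start_days)
  horizon_h <- if (!is.null(traj$horizon_days)) traj$horizon_days * 24 else
    (length(traj$times_h) - 1) * traj$output_step_h
  if (t_start_days < 0 || t_end_days * 24 > horizon_h + 1e-9)
    stop_lc("window [", t_start_days, ", ", t_end_days,
            "] days lies outside the trajectory span (",
            round(horizon_h / 24, 2), " days)")
  if (t_end_days == t_start_days) {
    return(tibble::tibble(particle = integer(), site_id = integer(),
                          status = character(), time_h = double(),
                          elapsed_h = double(), lon = double(),
                          lat = double(), dwell_h = double()))
  }
  sgn <- if (traj$mode == "forward") 1 else -1
  step <- traj$output_step_h
  n <- nrow(traj$lon)
  # Elapsed time of output column j for particle p (uniform time axis):
  # e_p(j) = e1_p + step * (j - 1) with e1_p = sgn * (t_1 - release_p).
  e1 <- sgn * (traj$times_h[1] - traj$meta$release_time_h)
  nt <- length(traj$times_h)
  j_lo <- pmax(1L, as.integer(ceiling((t_start_days * 24 - e1 - 1e-9) / step)) + 1L)
  j_hi <- pmin(nt, as.integer(ceiling((t_end_days * 24 - e1 - 1e-9) / step)))
  len <- pmax(0L, j_hi - j_lo + 1L)
  part <- rep.int(seq_len(n), len)
  cols <- sequence(len, from = pmin(j_lo, nt), by = 1L)
  idx <- cbind(part, cols)
  keep <- !is.na(traj$lon[idx])
  idx <- idx[keep, , drop = FALSE]
  tibble::tibble(
    particle = idx[, 1],
    site_id = traj$meta$site_id[idx[, 1]],
    status = traj$meta$status[idx[, 1]],
    time_h = traj$times_h[idx[, 2]],
    elapsed_h = e1[idx[, 1]] + step * (idx[, 2] - 1),
    lon = traj$lon[idx],
    lat = traj$lat[idx],
    dwell_h = step
  )
}
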