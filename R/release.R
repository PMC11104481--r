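#' Spawning configuration
#'
#' Release windows for larvae traced forward in time (spawning season) or
#' backward in time (settlement season, i.e. spawning + 30 days). Defaults
#' follow the study parameterization: forward releases 15 May–14 July (75%)
#' and 15 July–14 August (25%); backward releases 15 June–14 August (75%) and
#' 15 August–14 September (25%); 3000 larvae per site with at least one larva
#' released per site per hour throughout the windows. Window end dates are
#' inclusive; hour slots are half-open `[h, h + 1)`.
#'
#' @param forward_windows,backward_windows Tibbles with columns `start`, `end`
#'   (Dates, inclusive) and `fraction`; fractions must sum to 1 and windows
#'   must not overlap.
#' @param n_total Total larvae released per site.
#' @param min_per_hour Minimum releases per hour in every window hour.
#' @param year Calendar year used to build the default windows.
#' @return A list of class `spawning_config`.
#' @export
spawning_config <- function(forward_windows = NULL, backward_windows = NULL,
                            n_total = 3000, min_per_hour = 1, year = 2017) {
  d <- function(md) as.Date(sprintf("%d-%s", year, md))
  if (is.null(forward_windows)) {
    forward_windows <- tibble::tibble(
      start = c(d("05-15"), d("07-15")),
      end = c(d("07-14"), d("08-14")),
      fraction = c(0.75, 0.25)
    )
  }
  if (is.null(backward_windows)) {
    backward_windows <- tibble::tibble(
      start = c(d("06-15"), d("08-15")),
      end = c(d("08-14"), d("09-14")),
      fraction = c(0.75, 0.25)
    )
  }
  for (w in list(forward_windows, backward_windows)) {
    stopifnot(abs(sum(w$fraction) - 1) < 1e-9, all(w$end >= w$start))
    if (nrow(w) > 1) {
      o <- order(w$start)
      overlap <- if (inherits(w$start, "Date")) {
        any(w$start[o][-1] <= w$end[o][-nrow(w)])
      } else {
        any(w$start[o][-1] < w$end[o][-nrow(w)])
      }
      if (overlap) stop_lc("release windows overlap")
    }
  }
  structure(list(forward_windows = forward_windows,
                 backward_windows = backward_windows,
                 n_total = as.integer(n_total),
                 min_per_hour = as.integer(min_per_hour)),
            class = "spawning_config")
}

#' Larval drift-depth quota
#'
#' Default drift-depth distribution: 40% at 0–10 m, 40% at 10–20 m, 20% at
#' 20–30 m (ranged bands, uniform within band). Band intervals are half-open
#' `[lower, upper)` and must not overlap.
#'
#' @param bands Tibble with columns `lower`, `upper` and `weight`. Point
#'   depths are encoded as `lower == upper`.
#' @return A tibble of class `depth_quota`.
#' @export
depth_quota <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble::tibble(lower = c(0, 10, 20), upper = c(10, 20, 30),
                            weight = c(0.4, 0.4, 0.2))
  }
  bands <- tibble::as_tibble(bands)
  stopifnot(abs(sum(bands$weight) - 1) < 1e-9, all(bands$upper >= bands$lower))
  if (nrow(bands) > 1) {
    o <- order(bands$lower)
    ranged <- bands$upper > bands$lower
    if (any(bands$lower[o][-1] < bands$upper[o][-nrow(bands)] &
              (ranged[o][-1] | ranged[o][-nrow(bands)])))
      stop_lc("depth bands overlap")
  }
  class(bands) <- c("depth_quota", class(bands))
  bands
}

# Bed depths as a depth_quota (point bands).
bed_quota_as_depth_quota <- function(bed_depths) {
  depth_quota(tibble::tibble(lower = bed_depths$depth,
                             upper = bed_depths$depth,
                             weight = bed_depths$weight))
}

#' Assign depths by exact quota
#'
#' Band counts follow largest-remainder apportionment of `weight * n`, so the
#' configured proportions are realized exactly; within a ranged band depths
#' are uniform via the seeded RNG; point bands return the point value.
#'
#' @param n Number of depths to draw (>= 1).
#' @param quota A [depth_quota()].
#' @param seed Integer seed for the within-band placement.
#' @return Numeric vector of `n` depths (metres), grouped by band.
#' @export
#' @examples
#' table(cut(assign_depths(3000, depth_quota(), seed = 1), c(0, 10, 20, 30)))
assign_depths <- function(n, quota = depth_quota(), seed = NULL) {
  stopifnot(n >= 1)
  counts <- largest_remainder(quota$weight, n)
  with_seed(seed, {
    unlist(lapply(seq_len(nrow(quota)), function(b) {
      k <- counts[b]
      if (k == 0) return(numeric(0))
      if (quota$upper[b] > quota$lower[b]) {
        runif(k, quota$lower[b], quota$upper[b])
      } else {
        rep(quota$lower[b], k)
      }
    }))
  })
}

#' Schedule larval releases for one site
#'
#' Emits exactly `n_total` release events. Window counts are
#' round-half-up(`fraction` x `n_total`) with any remainder assigned to the
#' first window; within a window every hour receives `floor(N_w / H_w)` events
#' and the remainder is spread at evenly spaced hour indices, so every hour of
#' every window meets the minimum-per-hour constraint. Drift depths follow the
#' drift quota; backward-mode events are additionally released at mussel-bed
#' depths drawn from the site's bed-depth distribution.
#'
#' @param site One row of a [place_sites()] table (or any list with `site_id`,
#'   `lon`, `lat` and optionally `bed_depths`).
#' @param config A [spawning_config()].
#' @param mode `"forward"` (spawning releases) or `"backward"` (settlement
#'   releases to be traced back in time).
#' @param seed Integer seed (affects only within-band depth placement).
#' @param sim_start Calendar date of simulation hour 0.
#' @param drift_quota A [depth_quota()] for drift depths.
#' @return A `release_schedule` tibble: `site_id`, `mode`, `time_h`, `lon`,
#'   `lat`, `release_depth_m`, `drift_depth_m`, `window`.
#' @export
schedule_releases <- function(site, config = spawning_config(),
                              mode = c("forward", "backward"), seed = 1,
                              sim_start = NULL,
                              drift_quota = depth_quota()) {
  mode <- match.arg(mode)
  windows <- if (mode == "forward") config$forward_windows else config$backward_windows
  windows <- windows[order(windows$start), ]
  dated <- inherits(windows$start, "Date")
  if (is.null(sim_start)) sim_start <- if (dated) min(windows$start) else 0
  # Date windows are inclusive of both end dates; numeric windows are given
  # directly in hours as half-open [start, end).
  hours_per_window <- if (dated) {
    as.integer(windows$end - windows$start + 1) * 24L
  } else {
    as.integer(round(windows$end - windows$start))
  }
  total_hours <- sum(hours_per_window)
  if (config$n_total < total_hours * config$min_per_hour)
    stop_lc("cannot satisfy min-per-hour: n_total = ", config$n_total,
            " < ", total_hours, " window hours x min_per_hour = ",
            config$min_per_hour)

  n_w <- round_half_up(windows$fraction * config$n_total)
  n_w[1] <- n_w[1] + (config$n_total - sum(n_w))
  if (any(n_w < hours_per_window * config$min_per_hour))
    stop_lc("cannot satisfy min-per-hour within a window")

  start_h <- if (dated) as.numeric(windows$start - sim_start) * 24 else
    as.numeric(windows$start - sim_start)
  events <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    H <- hours_per_window[w]; N <- n_w[w]
    per_hour <- rep(N %/% H, H)
    r <- N %% H
    if (r > 0) {
      idx <- floor((0:(r - 1)) * H / r) + 1L
      per_hour[idx] <- per_hour[idx] + 1L
    }
    tibble::tibble(window = w,
                   time_h = start_h[w] + rep(0:(H - 1), per_hour))
  })

  n <- nrow(events)
  drift <- assign_depths(n, drift_quota, seed = seed)
  release <- if (mode == "backward") {
    bd <- if (!is.null(site$bed_depths)) {
      bdl <- site$bed_depths
      if (is.list(bdl) && !is.data.frame(bdl)) bdl <- bdl[[1]]
      bdl
    } else bed_depth_quota()
    assign_depths(n, bed_quota_as_depth_quota(bd),
                  seed = if (is.null(seed)) NULL else seed + 1L)
  } else drift

  out <- tibble::tibble(
    site_id = site$site_id[[1]], mode = mode, time_h = events$time_h,
    lon = site$lon[[1]], lat = site$lat[[1]],
    release_depth_m = release, drift_depth_m = drift,
    window = events$window
  )
  attr(out, "sim_start") <- sim_start
  class(out) <- c("release_schedule", class(out))
  out
}

#' Schedule releases for every site in a site set
#'
#' @param sites A [place_sites()] table.
#' @inheritParams schedule_releases
#' @return A `release_schedule` tibble covering all sites; seeds are offset per
#'   site so depth draws differ between sites but remain reproducible.
#' @export
schedule_all_releases <- function(sites, config = spawning_config(),
                                  mode = c("forward", "backward"), seed = 1,
                                  sim_start = NULL,
                                  drift_quota = depth_quota()) {
  mode <- match.arg(mode)
  windows <- if (mode == "forward") config$forward_windows else config$backward_windows
  if (is.null(sim_start)) sim_start <- min(windows$start)
  out <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    schedule_releases(sites[i, ], config, mode,
                      seed = if (is.null(seed)) NULL else seed + 10L * i,
                      sim_start = sim_start, drift_quota = drift_quota)
  })
  attr(out, "sim_start") <- sim_start
  class(out) <- c("release_schedule", class(out))
  out
}

#' Temperature–development model for mussel larvae
#'
#' Days from release to settlement as a logarithmic function of water
#' temperature: `y = a * ln(x) + b`. The default coefficients are the fitted
#' curve `y = -28.06 ln(x) + 101.32` (R^2 = 0.7545) compiled from published
#' rearing experiments.
#'
#' @param a Slope of the log term, days.
#' @param b Intercept, days.
#' @param r_squared Fit quality of the source regression (metadata).
#' @return A list of class `development_model`.
#' @export
development_model <- function(a = -28.06, b = 101.32, r_squared = 0.7545) {
  structure(list(a = a, b = b, r_squared = r_squared),
            class = "development_model")
}

#' Larval development time at a given temperature
#'
#' @param temperature_C Water temperature, degrees C (> 0; vectorized).
#' @param model A [development_model()].
#' @return Days until settlement.
#' @export
#' @examples
#' development_time(1)   # 101.32 days: the model intercept
#' development_time(15)
development_time <- function(temperature_C, model = development_model()) {
  if (any(!is.finite(temperature_C)) || any(temperature_C <= 0))
    stop_lc("development model is defined for temperature > 0 only")
  model$a * log(temperature_C) + model$b
}

#' Mean development time at a site from modeled temperatures
#'
#' Averages [development_time()] over hourly temperatures sampled at the site
#' position and drift depth across a time window. Only water cells enter the
#' interpolation stencil, so land temperatures never contribute.
#'
#' @param site One row of a site table (`lon`, `lat`).
#' @param field A [make_flow_field()] object.
#' @param window_h Length-2 numeric: start and end of the window, hours since
#'   field start (inclusive endpoints, hourly sampling).
#' @param model A [development_model()].
#' @param depth Sampling depth, metres.
#' @return Mean development time, days.
#' @export
site_mean_development_time <- function(site, field, window_h,
                                       model = development_model(), depth = 5) {
  stopifnot(length(window_h) == 2, window_h[2] >= window_h[1])
  if (window_h[1] < field$times_h[1] - 1e-9 ||
        window_h[2] > tail(field$times_h, 1) + 1e-9)
    stop_lc("window outside the field's time axis")
  tt <- seq(window_h[1], window_h[2], by = 1)
  temps <- sample_temperature(field, site$lon[[1]], site$lat[[1]], depth, tt)
  mean(development_time(temps, model))
}
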