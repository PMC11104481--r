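#' Settlement grid specification
#'
#' The settlement scoring grid and competency rules: larvae may settle where
#' water depth is below `depth_threshold` during the competency window
#' (default days 27–33 after release, the pelagic larval duration band).
#'
#' @param resolution Grid resolution, degrees (default 0.015).
#' @param depth_threshold Maximum settling depth, metres (default 10).
#' @param competency_window_days Length-2: start and end of the competency
#'   window, days since release.
#' @return A list of class `settlement_grid_spec`.
#' @export
settlement_grid_spec <- function(resolution = 0.015, depth_threshold = 10,
                                 competency_window_days = c(27, 33)) {
  stopifnot(resolution > 0,
            competency_window_days[1] < competency_window_days[2])
  structure(list(resolution = resolution, depth_threshold = depth_threshold,
                 competency_window_days = competency_window_days),
            class = "settlement_grid_spec")
}

# Settlement grid geometry derived from the bathymetry extent; shallow mask
# evaluated at cell centres.
settlement_grid <- function(bathy, spec) {
  res <- spec$resolution
  nx <- max(1L, round(diff(range(bathy$lon_edges)) / res))
  ny <- max(1L, round(diff(range(bathy$lat_edges)) / res))
  lon_edges <- bathy$lon_edges[1] + 0:nx * res
  lat_edges <- bathy$lat_edges[1] + 0:ny * res
  list(lon_edges = lon_edges, lat_edges = lat_edges,
       lon_centers = lon_edges[-1] - res / 2,
       lat_centers = lat_edges[-1] - res / 2,
       nx = nx, ny = ny, resolution = res)
}

grid_signature <- function(grid, spec) {
  c(grid$lon_edges[1], grid$lat_edges[1], grid$nx, grid$ny, grid$resolution,
    spec$depth_threshold, spec$competency_window_days)
}

#' Per-larva settlement probability map
#'
#' For each larva, the fraction of the competency window spent in each grid
#' cell with water depth below the threshold: a larva that spends 50% of the
#' settling period in one shallow cell and 10% in another gets weights 0.50
#' and 0.10 for those cells. Cells at or beyond the depth threshold score 0;
#' larvae lost from the domain (or halted on the coast) score 0 everywhere;
#' trajectories shorter than the window start are flagged immature and score 0.
#'
#' @param traj A `trajectory_set`.
#' @param bathy The `bathy_grid` supplying depths.
#' @param spec A [settlement_grid_spec()].
#' @return A `settlement_weights` tibble: `particle`, `site_id`, `ix`, `iy`,
#'   `weight`, with the grid geometry attached as attributes. Each larva's
#'   weights sum to at most 1; zero-weight larvae carry no rows but are
#'   counted in `attr(, "n_larvae")`.
#' @export
settlement_probability_map <- function(traj, bathy, spec = settlement_grid_spec()) {
  grid <- settlement_grid(bathy, spec)
  w0 <- spec$competency_window_days[1]
  w1 <- spec$competency_window_days[2]
  window_h <- (w1 - w0) * 24
  horizon_h <- if (!is.null(traj$horizon_days)) traj$horizon_days * 24 else
    (length(traj$times_h) - 1) * traj$output_step_h
  immature <- horizon_h < w0 * 24
  empty <- tibble::tibble(particle = integer(), site_id = integer(),
                          ix = integer(), iy = integer(), weight = double())
  out <- if (immature) empty else {
    pd <- positions_during(traj, w0, min(w1, horizon_h / 24)) |>
      dplyr::filter(.data$status == "drifting")
    if (nrow(pd) == 0) empty else {
      pd |>
        dplyr::mutate(ix = bin_index(.data$lon, grid$lon_edges),
                      iy = bin_index(.data$lat, grid$lat_edges)) |>
        dplyr::filter(!is.na(.data$ix), !is.na(.data$iy)) |>
        dplyr::mutate(
          depth = depth_at(bathy, grid$lon_centers[.data$ix],
                           grid$lat_centers[.data$iy])
        ) |>
        dplyr::filter(!is.na(.data$depth),
                      .data$depth < spec$depth_threshold) |>
        dplyr::group_by(.data$particle, .data$site_id, .data$ix, .data$iy) |>
        dplyr::summarise(weight = sum(.data$dwell_h) / window_h,
                         .groups = "drop")
    }
  }
  attr(out, "grid") <- grid
  attr(out, "spec") <- spec
  attr(out, "signature") <- grid_signature(grid, spec)
  attr(out, "n_larvae") <- nrow(traj$lon)
  attr(out, "immature") <- immature
  attr(out, "released") <- dplyr::count(traj$meta, .data$site_id,
                                        name = "released")
  class(out) <- c("settlement_weights", class(out))
  out
}

#' Sum per-larva settlement maps into a settlement field
#'
#' @param weights A `settlement_weights` tibble (or a list of them on the same
#'   grid).
#' @return A `settlement_field` tibble: `ix`, `iy`, `lon`, `lat`, `mass`
#'   (summed settlement probability, larvae-equivalents). Total mass never
#'   exceeds the number of larvae.
#' @export
sum_settlement <- function(weights) {
  if (!inherits(weights, "settlement_weights") && is.list(weights)) {
    sigs <- lapply(weights, attr, "signature")
    if (length(unique(lapply(sigs, paste, collapse = "|"))) > 1)
      stop_lc("settlement maps are on different grids")
    grid <- attr(weights[[1]], "grid")
    spec <- attr(weights[[1]], "spec")
    n_larvae <- sum(vapply(weights, attr, numeric(1), which = "n_larvae"))
    weights_all <- dplyr::bind_rows(weights)
  } else {
    grid <- attr(weights, "grid")
    spec <- attr(weights, "spec")
    n_larvae <- attr(weights, "n_larvae")
    weights_all <- weights
  }
  out <- weights_all |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(mass = sum(.data$weight), .groups = "drop") |>
    dplyr::mutate(lon = grid$lon_centers[.data$ix],
                  lat = grid$lat_centers[.data$iy]) |>
    dplyr::select("ix", "iy", "lon", "lat", "mass")
  attr(out, "grid") <- grid
  attr(out, "spec") <- spec
  attr(out, "n_larvae") <- n_larvae
  class(out) <- c("settlement_field", class(out))
  out
}

#' Grid-cell catchments of study sites
#'
#' The set of settlement cells attributed to each site: cells whose centre
#' lies within `radius` of the site and whose depth is below the settlement
#' threshold. Overlapping catchments (sites closer than twice the radius that
#' share cells) trigger a warning.
#'
#' @param sites A [place_sites()] table.
#' @param bathy The `bathy_grid`.
#' @param spec A [settlement_grid_spec()].
#' @param radius Capture radius, degrees (default 0.03, two cells at 0.015).
#' @return A `site_catchments` tibble: `site_id`, `ix`, `iy`, `lon`, `lat`.
#' @export
site_catchments <- function(sites, bathy, spec = settlement_grid_spec(),
                            radius = 0.03) {
  grid <- settlement_grid(bathy, spec)
  cells <- tidyr::expand_grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny)) |>
    dplyr::mutate(lon = grid$lon_centers[.data$ix],
                  lat = grid$lat_centers[.data$iy],
                  depth = depth_at(bathy, .data$lon, .data$lat)) |>
    dplyr::filter(!is.na(.data$depth), .data$depth < spec$depth_threshold)
  out <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    d2 <- (cells$lon - sites$lon[i])^2 + (cells$lat - sites$lat[i])^2
    dplyr::mutate(cells[d2 <= radius^2, c("ix", "iy", "lon", "lat")],
                  site_id = sites$site_id[i])
  }) |>
    dplyr::select("site_id", "ix", "iy", "lon", "lat")
  dup <- out |>
    dplyr::count(.data$ix, .data$iy) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    warn(paste0("site catchments overlap on ", nrow(dup),
                " cell(s); sites closer than 2 x radius"))
  attr(out, "grid") <- grid
  attr(out, "spec") <- spec
  attr(out, "radius") <- radius
  attr(out, "signature") <- grid_signature(grid, spec)
  class(out) <- c("site_catchments", class(out))
  out
}

#' Site-to-site connectivity matrix
#'
#' Percentage of larvae transferred from each origin site to each destination
#' catchment: `value(i, j) = 100 * sum of catchment-j settlement weights of
#' larvae released at i / released(i)`. The diagonal is local retention. In
#' backward mode rows are the settlement (release) sites and columns the
#' inferred source sites; the numbers are computed identically.
#'
#' @param weights A `settlement_weights` tibble with per-larva origin sites.
#' @param catchments A [site_catchments()] table on the same grid.
#' @param released Named vector or tibble (`site_id`, `released`) of release
#'   counts per origin; defaults to the counts recorded in `weights`.
#' @param direction `"forward"` or `"backward"` (interpretation tag).
#' @return An object of class `connectivity_matrix`: `values` (origin x
#'   destination percentages), `released`, `direction`, `site_ids`.
#' @export
connectivity_matrix <- function(weights, catchments, released = NULL,
                                direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!identical(attr(weights, "signature"), attr(catchments, "signature")))
    stop_lc("weights and catchments were built on different grids")
  if (is.null(released)) released <- attr(weights, "released")
  if (is.data.frame(released))
    released <- setNames(released$released, released$site_id)
  site_ids <- sort(unique(c(catchments$site_id,
                            as.integer(names(released)))))
  if (!all(unique(weights$site_id) %in% site_ids))
    stop_lc("weights contain unknown origin site(s): ",
            paste(setdiff(unique(weights$site_id), site_ids), collapse = ", "))
  k <- length(site_ids)
  vals <- matrix(0, k, k, dimnames = list(origin = site_ids,
                                          destination = site_ids))
  hits <- dplyr::inner_join(
    weights,
    dplyr::select(tibble::as_tibble(catchments), dest = "site_id", "ix", "iy"),
    by = c("ix", "iy"), relationship = "many-to-many"
  ) |>
    dplyr::group_by(.data$site_id, .data$dest) |>
    dplyr::summarise(mass = sum(.data$weight), .groups = "drop")
  rel <- released[as.character(site_ids)]
  if (any(is.na(rel)))
    stop_lc("missing release counts for site(s): ",
            paste(site_ids[is.na(rel)], collapse = ", "))
  for (r in seq_len(nrow(hits))) {
    i <- match(hits$site_id[r], site_ids)
    j <- match(hits$dest[r], site_ids)
    vals[i, j] <- 100 * hits$mass[r] / rel[i]
  }
  structure(list(values = vals, released = setNames(as.numeric(rel), site_ids),
                 direction = direction, site_ids = site_ids),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", length(x$site_ids), " sites, direction ",
      x$direction, "; mean retention ",
      round(mean(diag(x$values)), 2), "%\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) x$values

#' Local retention per site
#'
#' The diagonal of the connectivity matrix: the percentage of released larvae
#' settling back into the origin catchment.
#'
#' @param cm A [connectivity_matrix()].
#' @return Named numeric vector, percent.
#' @export
retention <- function(cm) {
  setNames(diag(cm$values), cm$site_ids)
}

#' Donor and recipient degree per site
#'
#' Counts of exchange partners using the display-threshold rule: an off-
#' diagonal transfer counts only if it is nonzero when rounded to
#' `digits` decimals (matching printed connectivity tables, whose blank cells
#' round to 0.00). `n_donated_to` is the number of sites a site exports to;
#' `n_received_from` the number of sites it imports from.
#'
#' @param cm A [connectivity_matrix()].
#' @param digits Display rounding used for the zero threshold (default 2).
#' @return A tibble: `site_id`, `n_donated_to`, `n_received_from`.
#' @export
connectivity_degrees <- function(cm, digits = 2) {
  disp <- round(cm$values, digits)
  diag(disp) <- 0
  tibble::tibble(
    site_id = cm$site_ids,
    n_donated_to = as.integer(rowSums(disp > 0)),
    n_received_from = as.integer(colSums(disp > 0))
  )
}

#' @export
tidy.connectivity_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$values), .name_repair = "minimal") |>
    setNames(c("origin", "destination", "pct")) |>
    dplyr::mutate(origin = as.integer(as.character(.data$origin)),
                  destination = as.integer(as.character(.data$destination)),
                  direction = x$direction)
}

#' @export
glance.connectivity_matrix <- function(x, ...) {
  deg <- connectivity_degrees(x)
  tibble::tibble(
    n_sites = length(x$site_ids),
    direction = x$direction,
    mean_retention_pct = mean(diag(x$values)),
    total_transfer_pct = mean(rowSums(x$values)),
    median_donors = median(deg$n_donated_to),
    median_recipients = median(deg$n_received_from)
  )
}
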