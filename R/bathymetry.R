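#' Specify a semi-enclosed fjord basin
#'
#' A fjord is carved into the coastal land frame of a synthetic domain: a
#' rectangular shallow basin connected to the open interior water by a narrow
#' strait. Units are grid cells except `at`, the along-coast position in
#' degrees (latitude for E/W coasts, longitude for N/S coasts).
#'
#' @param side Coast the fjord indents: `"E"`, `"W"`, `"N"` or `"S"`.
#' @param at Along-coast position of the strait centre, degrees.
#' @param basin_len Basin extent into the land frame, cells.
#' @param basin_width Basin extent along the coast, cells.
#' @param strait_len Strait length, cells.
#' @param strait_width Strait width, cells (1 = a single-cell channel).
#' @return A list of class `fjord_spec`.
#' @export
fjord_spec <- function(side = "E", at = 58, basin_len = 4, basin_width = 3,
                       strait_len = 5, strait_width = 1) {
  side <- match.arg(side, c("E", "W", "N", "S"))
  stopifnot(basin_len >= 1, basin_width >= 1, strait_len >= 1, strait_width >= 1)
  structure(list(side = side, at = at, basin_len = basin_len,
                 basin_width = basin_width, strait_len = strait_len,
                 strait_width = strait_width), class = "fjord_spec")
}

# Evaluate code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic coastal bathymetry
#'
#' Builds a regular lon/lat grid holding a coastal basin: a land frame around
#' the domain, optional islands, optional semi-enclosed fjords connected to the
#' open water by narrow straits, and water depth increasing linearly with
#' distance from the nearest coast (a shallow fringe suitable for mussel beds,
#' a deep interior). Cells are half-open intervals `[edge_i, edge_{i+1})`;
#' depth is metres positive-down and `NA` on land; land lives in `land_mask`.
#'
#' @param lon_range,lat_range Domain extent, degrees (length-2, ascending).
#' @param step Grid step, degrees (> 0). Default 0.015, the settlement grid
#'   resolution used throughout.
#' @param land_frame Width of the land frame around the domain, degrees. Use 0
#'   for an all-water sloped shelf.
#' @param islands Either an integer number of randomly placed circular islands
#'   or a list of `list(lon, lat, radius)` specs (degrees).
#' @param fjords List of [fjord_spec()] objects (possibly empty).
#' @param depth_per_cell Depth gained per cell of distance from land, metres.
#' @param depth_max Depth cap, metres.
#' @param seed Integer seed controlling random island placement; the result is
#'   bitwise reproducible for a given configuration and seed.
#' @return An object of class `bathy_grid`: a list with `lon_edges`,
#'   `lat_edges`, `lon_centers`, `lat_centers`, `depth` (lon x lat matrix),
#'   `land_mask`, `dist_land` (cells), `fjords` (tibble of carved rectangles)
#'   and `step`.
#' @export
#' @examples
#' b <- make_coastal_bathymetry(c(10, 10.3), c(57, 57.3), seed = 1)
#' mean(b$land_mask)
make_coastal_bathymetry <- function(lon_range = c(10, 12), lat_range = c(57, 59),
                                    step = 0.015, land_frame = 0.15,
                                    islands = 2,
                                    fjords = list(fjord_spec(side = "E", at = mean(lat_range))),
                                    depth_per_cell = 2.5, depth_max = 60,
                                    seed = 1) {
  if (step <= 0) stop_lc("grid step must be > 0")
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0)
    stop_lc("degenerate domain extent")
  nx <- round(diff(lon_range) / step)
  ny <- round(diff(lat_range) / step)
  if (nx < 4 || ny < 4) stop_lc("degenerate domain extent: too few cells")
  lon_edges <- lon_range[1] + 0:nx * step
  lat_edges <- lat_range[1] + 0:ny * step
  lon_c <- lon_edges[-1] - step / 2
  lat_c <- lat_edges[-1] - step / 2

  fw <- round(land_frame / step)
  land <- matrix(FALSE, nx, ny)
  if (fw > 0) {
    land[c(seq_len(fw), nx - fw + seq_len(fw)), ] <- TRUE
    land[, c(seq_len(fw), ny - fw + seq_len(fw))] <- TRUE
  }

  # Islands: circular land patches in the open interior.
  if (is.numeric(islands) && length(islands) == 1) {
    n_isl <- as.integer(islands)
    islands <- if (n_isl > 0) with_seed(seed, {
      lapply(seq_len(n_isl), function(i) {
        list(lon = runif(1, lon_range[1] + land_frame + 0.3,
                         lon_range[2] - land_frame - 0.3),
             lat = runif(1, lat_range[1] + land_frame + 0.3,
                         lat_range[2] - land_frame - 0.3),
             radius = runif(1, 2, 4) * step)
      })
    }) else list()
  }
  for (isl in islands) {
    dd <- outer(lon_c - isl$lon, lat_c - isl$lat,
                function(dx, dy) sqrt(dx^2 + dy^2))
    land[dd <= isl$radius] <- TRUE
  }

  # Fjords: carve water into the land frame.
  fj_rows <- list()
  for (k in seq_along(fjords)) {
    fj <- fjords[[k]]
    if (!inherits(fj, "fjord_spec")) fj <- do.call(fjord_spec, fj)
    need <- fj$strait_len + fj$basin_len
    if (fw == 0 || need > fw - 1)
      stop_lc("fjord spec does not fit within the land frame (needs ",
              need + 1, " cells, frame is ", fw, ")")
    along_c <- if (fj$side %in% c("E", "W")) lat_c else lon_c
    j0 <- which.min(abs(along_c - fj$at))
    half_b <- (fj$basin_width - 1) %/% 2
    half_s <- (fj$strait_width - 1) %/% 2
    jb <- max(1, j0 - half_b):min(length(along_c), j0 - half_b + fj$basin_width - 1)
    js <- max(1, j0 - half_s):min(length(along_c), j0 - half_s + fj$strait_width - 1)
    ii_water_end <- switch(fj$side, E = nx - fw, W = fw + 1,
                           N = ny - fw, S = fw + 1)
    dir <- if (fj$side %in% c("E", "N")) 1L else -1L
    i_strait <- ii_water_end + dir * seq_len(fj$strait_len)
    i_basin <- ii_water_end + dir * (fj$strait_len + seq_len(fj$basin_len))
    if (fj$side %in% c("E", "W")) {
      land[i_strait, js] <- FALSE
      land[i_basin, jb] <- FALSE
      cells_i <- range(c(i_strait, i_basin)); cells_j <- range(c(js, jb))
      basin_i <- range(i_basin); basin_j <- range(jb)
    } else {
      land[js, i_strait] <- FALSE
      land[jb, i_basin] <- FALSE
      cells_i <- range(c(js, jb)); cells_j <- range(c(i_strait, i_basin))
      basin_i <- range(jb); basin_j <- range(i_basin)
    }
    fj_rows[[k]] <- tibble::tibble(
      fjord_id = k, side = fj$side,
      lon_min = lon_edges[cells_i[1]], lon_max = lon_edges[cells_i[2] + 1],
      lat_min = lat_edges[cells_j[1]], lat_max = lat_edges[cells_j[2] + 1],
      basin_lon_min = lon_edges[basin_i[1]],
      basin_lon_max = lon_edges[basin_i[2] + 1],
      basin_lat_min = lat_edges[basin_j[1]],
      basin_lat_max = lat_edges[basin_j[2] + 1],
      strait_width = fj$strait_width
    )
  }

  dist_land <- dist_to_land_cells(land, border_is_land = TRUE)
  depth <- pmin(depth_per_cell * dist_land, depth_max)
  depth[land] <- NA_real_

  out <- structure(list(
    lon_edges = lon_edges, lat_edges = lat_edges,
    lon_centers = lon_c, lat_centers = lat_c,
    depth = depth, land_mask = land, dist_land = dist_land,
    fjords = if (length(fj_rows)) dplyr::bind_rows(fj_rows) else
      empty_fjord_tbl(),
    step = step, frame_cells = fw
  ), class = "bathy_grid")
  validate_bathy(out)
  out
}

empty_fjord_tbl <- function() {
  tibble::tibble(fjord_id = integer(), side = character(),
                 lon_min = double(), lon_max = double(),
                 lat_min = double(), lat_max = double(),
                 basin_lon_min = double(), basin_lon_max = double(),
                 basin_lat_min = double(), basin_lat_max = double(),
                 strait_width = integer())
}

validate_bathy <- function(b) {
  stopifnot(all(diff(b$lon_edges) > 0), all(diff(b$lat_edges) > 0))
  water <- !b$land_mask
  if (!all(is.finite(b$depth[water])) || any(b$depth[water] <= 0))
    stop_lc("invalid bathymetry: depth must be finite and > 0 over water")
  stopifnot(identical(dim(b$depth), dim(b$land_mask)))
  invisible(b)
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat("<bathy_grid> ", length(x$lon_centers), "x", length(x$lat_centers),
      " cells @ ", x$step, " deg; land fraction ",
      round(mean(x$land_mask), 3), "; ", nrow(x$fjords), " fjord(s)\n", sep = "")
  invisible(x)
}

# Cell index of (lon, lat); NA outside the grid. Vectorized.
bathy_cell <- function(bathy, lon, lat) {
  ix <- bin_index(lon, bathy$lon_edges)
  iy <- bin_index(lat, bathy$lat_edges)
  list(ix = ix, iy = iy)
}

#' Test whether positions fall on water cells
#'
#' @param bathy A [make_coastal_bathymetry()] grid.
#' @param lon,lat Positions, degrees (vectorized).
#' @return Logical vector; `FALSE` for land cells and points outside the grid.
#' @export
is_water <- function(bathy, lon, lat) {
  cc <- bathy_cell(bathy, lon, lat)
  ok <- !is.na(cc$ix) & !is.na(cc$iy)
  out <- logical(length(lon))
  out[ok] <- !bathy$land_mask[cbind(cc$ix[ok], cc$iy[ok])]
  out
}

# Depth (m) at positions; NA on land/outside.
depth_at <- function(bathy, lon, lat) {
  cc <- bathy_cell(bathy, lon, lat)
  ok <- !is.na(cc$ix) & !is.na(cc$iy)
  out <- rep(NA_real_, length(lon))
  out[ok] <- bathy$depth[cbind(cc$ix[ok], cc$iy[ok])]
  out
}

# Is a position inside any carved fjord rectangle (basin + strait)?
in_fjord <- function(bathy, lon, lat) {
  out <- logical(length(lon))
  fj <- bathy$fjords
  for (k in seq_len(nrow(fj))) {
    out <- out | (lon >= fj$lon_min[k] & lon < fj$lon_max[k] &
                    lat >= fj$lat_min[k] & lat < fj$lat_max[k])
  }
  out
}

#' @export
as_tibble.bathy_grid <- function(x, ...) {
  tidyr::expand_grid(iy = seq_along(x$lat_centers),
                     ix = seq_along(x$lon_centers)) |>
    dplyr::mutate(
      lon = x$lon_centers[.data$ix], lat = x$lat_centers[.data$iy],
      depth = x$depth[cbind(.data$ix, .data$iy)],
      land = x$land_mask[cbind(.data$ix, .data$iy)]
    ) |>
    dplyr::select("ix", "iy", "lon", "lat", "depth", "land")
}
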