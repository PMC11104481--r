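#' Default mussel-bed depth distribution
#'
#' Point-mass depth distribution of mussel beds used for backward (source
#' attribution) releases: 70% at 0.5 m, 10% each at 2, 4 and 6 m.
#'
#' @return A tibble with columns `depth` (m) and `weight`.
#' @export
bed_depth_quota <- function() {
  tibble::tibble(depth = c(0.5, 2, 4, 6), weight = c(0.7, 0.1, 0.1, 0.1))
}

#' Place study sites on a synthetic coast
#'
#' Places mussel-bed sites on shallow coastal water cells. One site is put at
#' the centre of every carved fjord basin (classified `"inner"`: large land
#' bodies restrict access to open water); the remaining sites are spread
#' evenly along the outer coastline fringe (classified `"outer"`). When the
#' domain has no enclosures all sites are `"outer"`.
#'
#' @param bathy A `bathy_grid`.
#' @param n_sites Number of sites (>= 2; at least one per fjord).
#' @param seed Integer seed (jitters the along-coast placement).
#' @param bed_depths Tibble of `(depth, weight)` attached to every site;
#'   defaults to [bed_depth_quota()].
#' @return A `site_set` tibble: `site_id`, `name`, `lon`, `lat`, `category`
#'   (`inner`/`outer`), and a `bed_depths` list-column. All sites lie on water.
#' @export
place_sites <- function(bathy, n_sites, seed = 1, bed_depths = bed_depth_quota()) {
  if (n_sites < 2) stop_lc("n_sites must be >= 2")
  stopifnot(abs(sum(bed_depths$weight) - 1) < 1e-9)
  nx <- length(bathy$lon_centers); ny <- length(bathy$lat_centers)
  water <- !bathy$land_mask

  # Fjord sites: basin centres (snapped to the nearest water cell).
  fj <- bathy$fjords
  inner <- tibble::tibble(lon = double(), lat = double())
  if (nrow(fj) > 0) {
    inner <- fj |>
      dplyr::mutate(lon = (.data$basin_lon_min + .data$basin_lon_max) / 2,
                    lat = (.data$basin_lat_min + .data$basin_lat_max) / 2) |>
      dplyr::select("lon", "lat")
    for (k in seq_len(nrow(inner))) {
      if (!is_water(bathy, inner$lon[k], inner$lat[k])) {
        idx <- which(water & in_fjord_mask(bathy))
        if (length(idx) == 0) stop_lc("fjord contains no water cells")
        ij <- arrayInd(idx, dim(water))
        dd <- (bathy$lon_centers[ij[, 1]] - inner$lon[k])^2 +
          (bathy$lat_centers[ij[, 2]] - inner$lat[k])^2
        best <- ij[which.min(dd), ]
        inner$lon[k] <- bathy$lon_centers[best[1]]
        inner$lat[k] <- bathy$lat_centers[best[2]]
      }
    }
  }
  n_inner <- nrow(inner)
  if (n_inner > n_sites) stop_lc("more fjords than requested sites")
  n_outer <- n_sites - n_inner

  # Outer candidates: shallow water cells hugging the land frame (or, in an
  # all-water domain, the domain border), excluding fjords and islands.
  cand <- which(water & bathy$dist_land <= 1.5)
  ij <- arrayInd(cand, dim(water))
  fc <- bathy$frame_cells
  near_frame <- ij[, 1] <= fc + 3 | ij[, 1] >= nx - fc - 2 |
    ij[, 2] <= fc + 3 | ij[, 2] >= ny - fc - 2
  lonv <- bathy$lon_centers[ij[, 1]]
  latv <- bathy$lat_centers[ij[, 2]]
  keep <- near_frame & !in_fjord(bathy, lonv, latv)
  if (!any(keep)) { # all-water shelf: fall back to all fringe cells
    keep <- !in_fjord(bathy, lonv, latv)
  }
  lonv <- lonv[keep]; latv <- latv[keep]
  if (length(lonv) < n_outer)
    stop_lc("fewer coastal water cells (", length(lonv),
            ") than requested sites (", n_outer, ")")

  # Order candidates by angle around the domain centre and take evenly spaced
  # positions (seeded phase) for an even along-coast spread.
  cx <- mean(range(bathy$lon_centers)); cy <- mean(range(bathy$lat_centers))
  ang <- atan2(latv - cy, lonv - cx)
  o <- order(ang, lonv, latv)
  lonv <- lonv[o]; latv <- latv[o]
  phase <- with_seed(seed, runif(1))
  picks <- unique(1 + floor(((seq_len(n_outer) - 1 + phase) / n_outer) *
                              length(lonv)) %% length(lonv))
  while (length(picks) < n_outer) {
    extra <- setdiff(seq_along(lonv), picks)
    picks <- c(picks, extra[seq_len(n_outer - length(picks))])
  }
  outer_sites <- tibble::tibble(lon = lonv[picks], lat = latv[picks])

  sites <- dplyr::bind_rows(
    dplyr::mutate(inner, category = "inner"),
    dplyr::mutate(outer_sites, category = "outer")
  ) |>
    dplyr::mutate(site_id = dplyr::row_number(),
                  name = sprintf("S%02d", .data$site_id),
                  bed_depths = list(bed_depths)) |>
    dplyr::select("site_id", "name", "lon", "lat", "category", "bed_depths")
  stopifnot(all(is_water(bathy, sites$lon, sites$lat)))
  class(sites) <- c("site_set", class(sites))
  sites
}

# Fjord membership as a matrix mask.
in_fjord_mask <- function(bathy) {
  nx <- length(bathy$lon_centers); ny <- length(bathy$lat_centers)
  grid_lon <- matrix(bathy$lon_centers, nx, ny)
  grid_lat <- matrix(bathy$lat_centers, nx, ny, byrow = TRUE)
  matrix(in_fjord(bathy, as.vector(grid_lon), as.vector(grid_lat)), nx, ny)
}
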