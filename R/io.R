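#' Write a flow field to NetCDF
#'
#' CF-style axes `lon`, `lat`, `depth`, `time` (hours since field start);
#' variables `u`, `v`, `temperature` plus the 2-D `bathymetry` (sea-floor
#' depth, `NA` on land).
#'
#' @param field A [make_flow_field()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flow_field <- function(field, path) {
  b <- field$bathy
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", b$lon_centers)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", b$lat_centers)
  dim_dep <- ncdf4::ncdim_def("depth", "m", field$depth_levels)
  dim_tim <- ncdf4::ncdim_def(
    "time", paste("hours since", format(field$start_date, "%Y-%m-%d 00:00:00")),
    field$times_h, unlim = TRUE)
  fv <- 9.969209968386869e36
  vu <- ncdf4::ncvar_def("u", "m s-1", list(dim_lon, dim_lat, dim_dep, dim_tim),
                         fv, prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s-1", list(dim_lon, dim_lat, dim_dep, dim_tim),
                         fv, prec = "double")
  vt <- ncdf4::ncvar_def("temperature", "degC",
                         list(dim_lon, dim_lat, dim_dep, dim_tim), fv,
                         prec = "double")
  vb <- ncdf4::ncvar_def("bathymetry", "m", list(dim_lon, dim_lat), fv,
                         prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv, vt, vb))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, field$u)
  ncdf4::ncvar_put(nc, vv, field$v)
  ncdf4::ncvar_put(nc, vt, field$temperature)
  ncdf4::ncvar_put(nc, vb, b$depth)
  ncdf4::ncatt_put(nc, 0, "grid_step_deg", b$step)
  ncdf4::ncatt_put(nc, 0, "frame_cells", b$frame_cells)
  invisible(path)
}

#' Read a flow field from NetCDF
#'
#' Reads files produced by [write_flow_field()]; the bathymetry grid is
#' reconstructed from the stored sea-floor depth (cells with missing depth are
#' land).
#'
#' @param path NetCDF file.
#' @return A `flow_field` object.
#' @export
read_flow_field <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon_c <- as.vector(nc$dim$lon$vals)
  lat_c <- as.vector(nc$dim$lat$vals)
  step <- ncdf4::ncatt_get(nc, 0, "grid_step_deg")$value
  if (!is.numeric(step) || length(step) != 1 || is.na(step))
    step <- diff(lon_c[1:2])
  depth2d <- ncdf4::ncvar_get(nc, "bathymetry")
  land <- is.na(depth2d)
  bathy <- structure(list(
    lon_edges = c(lon_c - step / 2, tail(lon_c, 1) + step / 2),
    lat_edges = c(lat_c - step / 2, tail(lat_c, 1) + step / 2),
    lon_centers = lon_c, lat_centers = lat_c,
    depth = depth2d, land_mask = land,
    dist_land = dist_to_land_cells(land, border_is_land = TRUE),
    fjords = empty_fjord_tbl(),
    step = step,
    frame_cells = {
      fc <- ncdf4::ncatt_get(nc, 0, "frame_cells")$value
      if (is.numeric(fc) && length(fc) == 1 && !is.na(fc)) fc else 0L
    }
  ), class = "bathy_grid")
  tunits <- nc$dim$time$units
  start_date <- as.Date(sub("hours since ", "", tunits))
  dims4 <- c(length(lon_c), length(lat_c), length(nc$dim$depth$vals),
             length(nc$dim$time$vals))
  get4 <- function(name) array(ncdf4::ncvar_get(nc, name, collapse_degen = FALSE),
                               dims4)
  structure(list(times_h = as.vector(nc$dim$time$vals),
                 depth_levels = as.vector(nc$dim$depth$vals),
                 u = get4("u"), v = get4("v"),
                 temperature = get4("temperature"),
                 start_date = start_date, bathy = bathy),
            class = "flow_field")
}

#' Write trajectories to NetCDF
#'
#' Dimensions `particle` and `time`; variables `lon`, `lat` and per-particle
#' `status` codes (0 drifting, 1 lost_domain, 2 halted).
#'
#' @param traj A `trajectory_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectories_nc <- function(traj, path) {
  np <- nrow(traj$lon)
  dim_p <- ncdf4::ncdim_def("particle", "", seq_len(np),
                            create_dimvar = FALSE)
  dim_t <- ncdf4::ncdim_def("time", "hours", traj$times_h)
  fv <- 9.969209968386869e36
  vlon <- ncdf4::ncvar_def("lon", "degrees_east", list(dim_p, dim_t), fv)
  vlat <- ncdf4::ncvar_def("lat", "degrees_north", list(dim_p, dim_t), fv)
  vst <- ncdf4::ncvar_def("status", "", list(dim_p), -1, prec = "integer")
  nc <- ncdf4::nc_create(path, list(vlon, vlat, vst))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vlon, traj$lon)
  ncdf4::ncvar_put(nc, vlat, traj$lat)
  codes <- c(drifting = 0L, lost_domain = 1L, halted = 2L)
  ncdf4::ncvar_put(nc, vst, unname(codes[traj$meta$status]))
  ncdf4::ncatt_put(nc, 0, "mode", traj$mode)
  invisible(path)
}

#' Write / read a site table as CSV
#'
#' Columns `site_id`, `name`, `lon`, `lat`, `category` (bed-depth
#' distributions are configuration, not site data, and are re-attached on
#' read).
#'
#' @param sites A [place_sites()] table.
#' @param path CSV file.
#' @return `path` / a `site_set` tibble.
#' @export
write_sites_csv <- function(sites, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(sites), "site_id", "name",
                                 "lon", "lat", "category"), path)
  invisible(path)
}

#' @rdname write_sites_csv
#' @param bed_depths Bed-depth tibble attached to every site on read.
#' @export
read_sites_csv <- function(path, bed_depths = bed_depth_quota()) {
  out <- readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(bed_depths = list(bed_depths))
  class(out) <- c("site_set", class(out))
  out
}

#' Write / read a release schedule as CSV
#'
#' @param schedule A [schedule_releases()] tibble.
#' @param path CSV file.
#' @return `path` / a `release_schedule` tibble.
#' @export
write_schedule_csv <- function(schedule, path) {
  readr::write_csv(tibble::as_tibble(schedule), path)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("release_schedule", class(out))
  out
}

#' Read a spawning configuration from YAML
#'
#' Expected layout: top-level keys `n_total`, `min_per_hour`, and
#' `forward_windows` / `backward_windows`, each a list of `start`, `end`
#' (ISO dates) and `fraction`.
#'
#' @param path YAML file.
#' @return A [spawning_config()].
#' @export
read_spawning_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  parse_windows <- function(ww) {
    if (is.null(ww)) return(NULL)
    dplyr::bind_rows(lapply(ww, function(w) {
      tibble::tibble(start = as.Date(w$start), end = as.Date(w$end),
                     fraction = w$fraction)
    }))
  }
  spawning_config(forward_windows = parse_windows(y$forward_windows),
                  backward_windows = parse_windows(y$backward_windows),
                  n_total = y$n_total %||% 3000,
                  min_per_hour = y$min_per_hour %||% 1)
}

#' Write a connectivity matrix as CSV
#'
#' Printed-table layout: rows are origin sites, columns destination sites,
#' percentages rounded to two decimals (full precision is retained in the
#' matrix object, only the file is rounded).
#'
#' @param cm A [connectivity_matrix()].
#' @param path CSV file.
#' @param digits Decimals written (default 2).
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(cm, path, digits = 2) {
  df <- tibble::as_tibble(round(cm$values, digits), rownames = "site_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @param direction Direction tag to attach on read.
#' @param released Optional release counts per site to attach.
#' @export
read_connectivity_csv <- function(path, direction = "forward",
                                  released = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.integer(df$site_id)
  vals <- as.matrix(df[, -1])
  dimnames(vals) <- list(origin = ids, destination = as.integer(colnames(vals)))
  if (is.null(released)) released <- setNames(rep(NA_real_, length(ids)), ids)
  structure(list(values = vals, released = released, direction = direction,
                 site_ids = ids), class = "connectivity_matrix")
}

#' Write / read a dosage matrix as CSV
#'
#' Individuals in rows (first column `id`), loci in columns; missing genotypes
#' are empty cells.
#'
#' @param x A `genotype_dataset` or dosage matrix.
#' @param path CSV file.
#' @return `path` / an integer dosage matrix with `NA` for missing.
#' @export
write_genotypes_csv <- function(x, path) {
  dos <- if (inherits(x, "genotype_dataset")) x$dosages else as.matrix(x)
  readr::write_csv(tibble::as_tibble(dos, rownames = "id"), path, na = "")
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  storage.mode(m) <- "integer"
  m
}

#' Read genotype dosages from a minimal VCF
#'
#' Consumes only the GT field of a diploid VCF: `0/0`, `0/1`, `1/1` (or
#' phased `|`) become alternate-allele dosages 0, 1, 2; `./.` becomes `NA`.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return Integer dosage matrix, individuals x loci.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_lc("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  to_dose <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  m <- apply(gt, 2, to_dose)
  m <- t(m) # individuals x loci
  colnames(m) <- rownames(gt)
  m
}

#' Read an admixture coefficient table from CSV
#'
#' Layout: an `id` column plus one numeric column per cluster; any extra
#' non-numeric columns (e.g. sampling site) are dropped.
#'
#' @param path CSV file.
#' @return A tibble suitable for [assign_lineages()].
#' @export
read_admixture_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  keep <- names(df) == "id" | vapply(df, is.numeric, logical(1))
  df[keep]
}

#' Write site catchments as GeoJSON polygons
#'
#' One MultiPolygon feature per site made of its catchment cell rectangles.
#'
#' @param catchments A [site_catchments()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catchments_geojson <- function(catchments, path) {
  grid <- attr(catchments, "grid")
  res <- grid$resolution
  feats <- catchments |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_map(function(g, key) {
      polys <- lapply(seq_len(nrow(g)), function(r) {
        x0 <- g$lon[r] - res / 2; x1 <- g$lon[r] + res / 2
        y0 <- g$lat[r] - res / 2; y1 <- g$lat[r] + res / 2
        list(list(list(x0, y0), list(x1, y0), list(x1, y1), list(x0, y1),
                  list(x0, y0)))
      })
      list(type = "Feature",
           properties = list(site_id = key$site_id),
           geometry = list(type = "MultiPolygon", coordinates = polys))
    })
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_lc("writing GeoJSON requires the jsonlite package")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
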