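#' @export
autoplot.bathy_grid <- function(object, ...) {
  df <- as_tibble.bathy_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$depth)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey30", direction = -1,
                                  name = "depth (m)") +
    ggplot2::coord_fixed(1 / cos(mean(df$lat) * pi / 180), expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' @export
autoplot.flow_field <- function(object, time_index = 1, depth_index = 1,
                                stride = 5, ...) {
  b <- object$bathy
  ii <- seq(1, length(b$lon_centers), by = stride)
  jj <- seq(1, length(b$lat_centers), by = stride)
  df <- tidyr::expand_grid(ix = ii, iy = jj) |>
    dplyr::mutate(lon = b$lon_centers[.data$ix], lat = b$lat_centers[.data$iy],
                  u = object$u[cbind(.data$ix, .data$iy, depth_index, time_index)],
                  v = object$v[cbind(.data$ix, .data$iy, depth_index, time_index)],
                  speed = sqrt(.data$u^2 + .data$v^2)) |>
    dplyr::filter(.data$speed > 0)
  sc <- 0.04 / max(df$speed, 1e-9)
  autoplot.bathy_grid(b) +
    ggplot2::geom_segment(
      data = df,
      ggplot2::aes(x = .data$lon, y = .data$lat,
                   xend = .data$lon + .data$u * sc,
                   yend = .data$lat + .data$v * sc),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
      color = "white", linewidth = 0.3, inherit.aes = FALSE)
}

#' @export
autoplot.settlement_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mass)) +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "settlement\nmass") +
    ggplot2::coord_fixed(1 / cos(mean(object$lat) * pi / 180)) +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tidy.connectivity_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$destination),
                                   factor(.data$origin))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$pct)) +
    ggplot2::scale_fill_viridis_c(trans = "sqrt", name = "% transferred") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "destination site", y = "origin site",
                  title = paste0(object$direction, " connectivity"))
}

#' @export
autoplot.krige_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = "value") +
    ggplot2::coord_fixed(1 / cos(mean(object$lat) * pi / 180)) +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Plot a sample of particle trajectories
#'
#' @param traj A `trajectory_set`.
#' @param n Number of particles to draw (sampled evenly).
#' @param bathy Optional `bathy_grid` to draw underneath.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj, n = 50, bathy = NULL) {
  np <- nrow(traj$lon)
  pick <- unique(round(seq(1, np, length.out = min(n, np))))
  df <- purrr::map_dfr(pick, function(p) {
    ok <- !is.na(traj$lon[p, ])
    tibble::tibble(particle = p, lon = traj$lon[p, ok], lat = traj$lat[p, ok],
                   step = seq_len(sum(ok)))
  })
  base <- if (!is.null(bathy)) autoplot.bathy_grid(bathy) else
    ggplot2::ggplot()
  base +
    ggplot2::geom_path(data = df,
                       ggplot2::aes(.data$lon, .data$lat,
                                    group = .data$particle,
                                    color = factor(.data$particle)),
                       linewidth = 0.2, alpha = 0.7, inherit.aes = FALSE) +
    ggplot2::guides(color = "none")
}
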