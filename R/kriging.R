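#' Fit an exponential variogram by weighted least squares
#'
#' Computes the empirical semivariogram of site values in binned lag classes
#' and fits the exponential model
#' `gamma(h) = nugget + psill * (1 - exp(-h / range))` by Cressie-weighted
#' least squares (weights `N_k / gamma(h_k)^2`).
#'
#' @param df Data frame with columns `lon`, `lat`, `value`.
#' @param n_bins Number of lag bins up to half the maximum pair distance.
#' @param nugget Fixed nugget, or `NULL` to estimate it.
#' @return A list of class `variogram_fit` with `nugget`, `psill`, `range_m`
#'   and the empirical semivariogram tibble.
#' @export
fit_variogram <- function(df, n_bins = 10, nugget = NULL) {
  stopifnot(all(c("lon", "lat", "value") %in% names(df)))
  n <- nrow(df)
  if (n < 4) stop_lc("variogram fitting needs at least 4 sites")
  lat0 <- mean(df$lat)
  x <- df$lon * m_per_deg_lon(lat0)
  y <- df$lat * m_per_deg_lat()
  dmat <- as.matrix(dist(cbind(x, y)))
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  h <- dmat[pairs]
  g <- (df$value[pairs[, 1]] - df$value[pairs[, 2]])^2 / 2
  hmax <- max(h) / 2
  bins <- seq(0, hmax, length.out = n_bins + 1)
  bin <- findInterval(h, bins, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= n_bins
  emp <- tibble::tibble(bin = bin[keep], h = h[keep], g = g[keep]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(h = mean(.data$h), gamma = mean(.data$g),
                     n_pairs = dplyr::n(), .groups = "drop")
  if (nrow(emp) < 3) { # too few lags to fit: fall back to moments
    emp <- tibble::tibble(bin = 1L, h = mean(h), gamma = mean(g),
                          n_pairs = length(h))
  }
  s2 <- stats::var(df$value)
  fixed_nugget <- !is.null(nugget)
  obj <- function(par) {
    ng <- if (fixed_nugget) nugget else exp(par[1])
    ps <- exp(par[if (fixed_nugget) 1 else 2])
    rg <- exp(par[if (fixed_nugget) 2 else 3])
    mod <- ng + ps * (1 - exp(-emp$h / rg))
    w <- emp$n_pairs / pmax(mod, 1e-12)^2
    sum(w * (emp$gamma - mod)^2)
  }
  start <- log(c(if (!fixed_nugget) max(s2 * 0.05, 1e-8),
                 max(s2, 1e-8), max(hmax / 3, 1)))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  p <- exp(fit$par)
  out <- if (fixed_nugget) {
    list(nugget = nugget, psill = p[1], range_m = p[2])
  } else {
    list(nugget = p[1], psill = p[2], range_m = p[3])
  }
  out$empirical <- emp
  out$convergence <- fit$convergence
  class(out) <- "variogram_fit"
  out
}

vgm_gamma <- function(h, vg) {
  vg$nugget + vg$psill * (1 - exp(-h / vg$range_m))
}

# Solve the ordinary kriging system for prediction points; falls back to
# inverse-distance weighting when the system is singular.
.krige_solve <- function(df, px, py, vg) {
  lat0 <- mean(df$lat)
  x <- df$lon * m_per_deg_lon(lat0)
  y <- df$lat * m_per_deg_lat()
  n <- length(x)
  G <- vgm_gamma(as.matrix(dist(cbind(x, y))), vg)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  D <- sqrt(outer(px, x, `-`)^2 + outer(py, y, `-`)^2)
  B <- rbind(t(vgm_gamma(D, vg)), 1)
  w <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(w)) {
    warn("kriging system is singular; falling back to inverse-distance weighting")
    Wi <- 1 / pmax(D, 1e-9)^2
    exact <- D < 1e-9
    Wi[rowSums(exact) > 0, ] <- 0
    Wi[exact] <- 1
    return(as.vector(Wi %*% df$value / rowSums(Wi)))
  }
  as.vector(t(w[seq_len(n), , drop = FALSE]) %*% df$value)
}

#' Kriging prediction at arbitrary points
#'
#' Ordinary kriging of site values with an exponential variogram. With a zero
#' nugget the predictor is exact at the site locations.
#'
#' @param df Data frame of observations: `lon`, `lat`, `value` (>= 4 rows).
#' @param newdata Data frame of prediction points: `lon`, `lat`.
#' @param variogram A [fit_variogram()] result, or `NULL` to fit one.
#' @return `newdata` with a `value` column of kriged predictions.
#' @export
krige_points <- function(df, newdata, variogram = NULL) {
  if (nrow(df) < 4) stop_lc("kriging needs at least 4 sites")
  df <- dplyr::filter(df, is.finite(.data$value))
  if (nrow(df) < 4) stop_lc("kriging needs at least 4 sites with finite values")
  if (stats::var(df$value) == 0) {
    return(dplyr::mutate(tibble::as_tibble(newdata), value = df$value[1]))
  }
  if (is.null(variogram)) variogram <- fit_variogram(df)
  lat0 <- mean(df$lat)
  px <- newdata$lon * m_per_deg_lon(lat0)
  py <- newdata$lat * m_per_deg_lat()
  dplyr::mutate(tibble::as_tibble(newdata),
                value = .krige_solve(df, px, py, variogram))
}

#' Kriged connectivity surface
#'
#' Interpolates per-site values (e.g. retention, import or export) to a fine
#' regular grid — by default 0.01 degrees, a touch finer than the 0.015-degree
#' settlement grid — by ordinary kriging with an exponential variogram fitted
#' to the empirical semivariogram. When a bathymetry is supplied, only water
#' cells are predicted.
#'
#' @param df Data frame of site values: `lon`, `lat`, `value` (>= 4 rows).
#' @param resolution Output grid resolution, degrees.
#' @param extent Length-4 extent `c(lon_min, lon_max, lat_min, lat_max)`;
#'   defaults to the bathymetry extent or the data bounding box.
#' @param variogram Optional [fit_variogram()] result.
#' @param bathy Optional `bathy_grid` used to mask land.
#' @return A `krige_surface` tibble: `lon`, `lat`, `value`, with the variogram
#'   attached as attribute `"variogram"`.
#' @export
krige_surface <- function(df, resolution = 0.01, extent = NULL,
                          variogram = NULL, bathy = NULL) {
  if (is.null(extent)) {
    extent <- if (!is.null(bathy)) {
      c(range(bathy$lon_edges), range(bathy$lat_edges))
    } else {
      c(range(df$lon), range(df$lat))
    }
  }
  lon_c <- seq(extent[1] + resolution / 2, extent[2], by = resolution)
  lat_c <- seq(extent[3] + resolution / 2, extent[4], by = resolution)
  grid <- tidyr::expand_grid(lat = lat_c, lon = lon_c)[, c("lon", "lat")]
  if (!is.null(bathy)) grid <- grid[is_water(bathy, grid$lon, grid$lat), ]
  if (is.null(variogram) && nrow(df) >= 4 &&
        stats::var(df$value[is.finite(df$value)]) > 0)
    variogram <- fit_variogram(dplyr::filter(df, is.finite(.data$value)))
  out <- krige_points(df, grid, variogram = variogram)
  attr(out, "variogram") <- variogram
  attr(out, "resolution") <- resolution
  class(out) <- c("krige_surface", class(out))
  out
}
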