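# Geodesy: the model domains span ~2 degrees, so positions are kept in
# lon/lat and converted to metres with an equirectangular local metric.
.R_EARTH <- 6371008.8
.M_PER_DEG_LAT <- pi * .R_EARTH / 180

m_per_deg_lat <- function() .M_PER_DEG_LAT

m_per_deg_lon <- function(lat) .M_PER_DEG_LAT * cos(lat * pi / 180)

# Round-half-up, used for window quotas (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

#' Largest-remainder integer apportionment
#'
#' Splits an integer total over categories in proportion to `weights` so the
#' realized counts are exact integers summing to `n`. Ties in the fractional
#' remainders are resolved in category order.
#'
#' @param weights Non-negative weights (need not sum to 1).
#' @param n Integer total to apportion.
#' @return Integer vector of counts, same length as `weights`, summing to `n`.
#' @export
#' @examples
#' largest_remainder(c(0.4, 0.4, 0.2), 3000)
largest_remainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, n >= 0)
  share <- weights / sum(weights) * n
  base <- floor(share)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Half-open cell binning [edge_i, edge_{i+1}); a position on an upper edge
# belongs to the next cell. Returns NA outside the grid.
bin_index <- function(x, edges) {
  i <- findInterval(x, edges)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

# Iterative chamfer-style distance transform (in cells) to the nearest land
# cell or, if `border_is_land`, to the domain border ring. Quasi-Euclidean
# (1 / sqrt(2) steps), iterated to convergence; grids here are small.
dist_to_land_cells <- function(land_mask, border_is_land = TRUE) {
  nx <- nrow(land_mask); ny <- ncol(land_mask)
  big <- nx + ny + 2
  d <- matrix(big, nx, ny)
  d[land_mask] <- 0
  pad <- if (border_is_land) 0 else big
  repeat {
    ex <- matrix(pad, nx + 2, ny + 2)
    ex[2:(nx + 1), 2:(ny + 1)] <- d
    cand <- pmin(
      ex[1:nx, 2:(ny + 1)], ex[3:(nx + 2), 2:(ny + 1)],
      ex[2:(nx + 1), 1:ny], ex[2:(nx + 1), 3:(ny + 2)]
    ) + 1
    diag_cand <- pmin(
      ex[1:nx, 1:ny], ex[3:(nx + 2), 1:ny],
      ex[1:nx, 3:(ny + 2)], ex[3:(nx + 2), 3:(ny + 2)]
    ) + sqrt(2)
    new_d <- pmin(d, cand, diag_cand)
    new_d[land_mask] <- 0
    if (max(abs(new_d - d)) < 1e-12) break
    d <- new_d
  }
  d
}

# Connected components of the water mask (4-neighbour flood fill), used for
# fjord connectivity checks and site placement.
water_components <- function(water_mask) {
  nx <- nrow(water_mask); ny <- ncol(water_mask)
  comp <- matrix(0L, nx, ny)
  next_id <- 0L
  todo <- which(water_mask & comp == 0L)
  while (length(todo) > 0) {
    next_id <- next_id + 1L
    frontier <- matrix(FALSE, nx, ny)
    frontier[todo[1]] <- TRUE
    while (any(frontier)) {
      comp[frontier] <- next_id
      ex <- matrix(FALSE, nx + 2, ny + 2)
      ex[2:(nx + 1), 2:(ny + 1)] <- frontier
      grown <- ex[1:nx, 2:(ny + 1)] | ex[3:(nx + 2), 2:(ny + 1)] |
        ex[2:(nx + 1), 1:ny] | ex[2:(nx + 1), 3:(ny + 2)]
      frontier <- grown & water_mask & comp == 0L
    }
    todo <- which(water_mask & comp == 0L)
  }
  comp
}

# Shared stop() helper with call suppressed.
stop_lc <- function(...) stop(..., call. = FALSE)
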