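# Internal planar-geometry and regular-grid helpers.
#
# All geometry in this package lives on a local planar projection in km:
# y runs south -> north and maps linearly to latitude, x runs land -> sea.
# At the 1-5 km scales of the survey design the planar approximation is
# exact enough that no geodesic code is needed.

#' Convert planar northing to latitude
#'
#' @param y northing in km on the local projection.
#' @param lat0 latitude (decimal degrees) at `y = 0`.
#' @param km_per_degree km of northing per degree of latitude.
#' @return latitude in decimal degrees.
#' @keywords internal
y_to_lat <- function(y, lat0, km_per_degree = 111) {
  lat0 + y / km_per_degree
}

#' 1-degree latitude bin label
#'
#' @param lat latitude in decimal degrees.
#' @return integer bin label (floor of latitude), matching the 1-degree
#'   binning of coastal upwelling index products.
#' @keywords internal
lat_bin_of <- function(lat) as.integer(floor(lat))

# cumulative along-polyline arc length (km); first vertex gets 0
polyline_arclength <- function(x, y) {
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

# Minimum Euclidean distance from each point to a polyline, vectorised
# over points and processed in chunks to bound memory.
dist_to_polyline <- function(px, py, vx, vy, chunk = 2000L) {
  stopifnot(length(vx) >= 2L, length(vx) == length(vy))
  n <- length(vx)
  ax <- vx[-n]; ay <- vy[-n]
  dx <- vx[-1] - ax; dy <- vy[-1] - ay
  len2 <- pmax(dx^2 + dy^2, .Machine$double.eps)
  out <- numeric(length(px))
  for (i0 in seq(1, length(px), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(px))
    tx <- outer(px[idx], ax, "-")
    ty <- outer(py[idx], ay, "-")
    tt <- (sweep(tx, 2, dx, "*") + sweep(ty, 2, dy, "*"))
    tt <- sweep(tt, 2, len2, "/")
    tt[tt < 0] <- 0
    tt[tt > 1] <- 1
    ex <- tx - sweep(tt, 2, dx, "*")
    ey <- ty - sweep(tt, 2, dy, "*")
    d2 <- ex^2 + ey^2
    out[idx] <- sqrt(d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))])
  }
  out
}

# Interpolate a point (and unit tangent / seaward normal) at arc-length
# position s along a polyline. Seaward is the +x side for a coastline
# running northwards.
polyline_point_at <- function(x, y, s_target) {
  s <- polyline_arclength(x, y)
  s_target <- pmin(pmax(s_target, 0), max(s))
  px <- stats::approx(s, x, xout = s_target, rule = 2)$y
  py <- stats::approx(s, y, xout = s_target, rule = 2)$y
  # tangent from a small arc-length step (backward at the far end,
  # where a forward step would clip to zero length)
  h <- max(s) * 1e-6 + 1e-9
  fwd <- s_target + h <= max(s)
  s2 <- ifelse(fwd, s_target + h, s_target - h)
  qx <- stats::approx(s, x, xout = s2, rule = 2)$y
  qy <- stats::approx(s, y, xout = s2, rule = 2)$y
  tx <- ifelse(fwd, qx - px, px - qx)
  ty <- ifelse(fwd, qy - py, py - qy)
  tl <- sqrt(tx^2 + ty^2)
  tl[tl == 0] <- 1
  tx <- tx / tl; ty <- ty / tl
  list(x = px, y = py, tx = tx, ty = ty, nx = ty, ny = -tx)
}

# --- regular-grid data frames ------------------------------------------
#
# A "grid frame" is a data frame with one row per cell centre (columns x, y
# at least) plus attributes xmin, ymin, res, nx, ny. Rows are ordered
# y-major (all x for the first y row, then the next y row).

make_grid_frame <- function(xmin, xmax, ymin, ymax, res) {
  if (res <= 0 || xmax <= xmin || ymax <= ymin) {
    stop("grid extent and resolution must be positive")
  }
  xs <- seq(xmin + res / 2, xmax, by = res)
  ys <- seq(ymin + res / 2, ymax, by = res)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  attr(g, "xmin") <- xmin
  attr(g, "ymin") <- ymin
  attr(g, "res") <- res
  attr(g, "nx") <- length(xs)
  attr(g, "ny") <- length(ys)
  g
}

# Row indices of the grid cells containing the points; NA outside the grid.
grid_cell_index <- function(grid, x, y) {
  res <- attr(grid, "res"); xmin <- attr(grid, "xmin"); ymin <- attr(grid, "ymin")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  ix <- floor((x - xmin) / res) + 1L
  iy <- floor((y - ymin) / res) + 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  idx <- (iy - 1L) * nx + ix
  idx[!ok] <- NA_integer_
  idx
}

# Nearest-cell extraction of one or more layers at point locations.
grid_extract <- function(grid, x, y, layers) {
  idx <- grid_cell_index(grid, x, y)
  out <- grid[ifelse(is.na(idx), 1L, idx), layers, drop = FALSE]
  out[is.na(idx), ] <- NA
  rownames(out) <- NULL
  out
}
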