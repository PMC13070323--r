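# Static habitat covariates at 1 km resolution: depth, distance to
# coast, shelf width, signed distance to capes, distance to estuaries,
# and binary substrate.

#' Smooth a coastline by an arc-length moving average
#'
#' Replaces each vertex by the mean position of all vertices within an
#' arc-length window centred on it (window truncated at the ends of the
#' polyline). A 200 km window removes promontory-scale structure, so
#' prominent capes appear as excursions of the high-resolution coastline
#' away from the smoothed one.
#'
#' @param coast data frame with columns `x`, `y` (ordered vertices, km).
#' @param window window length in km (default 200).
#' @return data frame `x`, `y`, `s` of the smoothed polyline (same number
#'   of vertices).
#' @export
smooth_coastline <- function(coast, window = 200) {
  if (window <= 0) stop("window must be positive")
  s <- polyline_arclength(coast$x, coast$y)
  if (window >= max(s)) stop("window must be smaller than the coastline arc length")
  n <- nrow(coast)
  # findInterval gives the last index with s[idx] <= bound
  lo <- findInterval(s - window / 2 - 1e-12, s) + 1L
  hi <- findInterval(s + window / 2 + 1e-12, s)
  lo <- pmax(lo, 1L); hi <- pmin(hi, n)
  csx <- cumsum(c(0, coast$x)); csy <- cumsum(c(0, coast$y))
  m <- hi - lo + 1
  out <- data.frame(x = (csx[hi + 1] - csx[lo]) / m,
                    y = (csy[hi + 1] - csy[lo]) / m)
  out$s <- polyline_arclength(out$x, out$y)
  out
}

#' Detect prominent capes
#'
#' Designates capes where the high-resolution coastline lies more than
#' `threshold` km from the smoothed coastline. Contiguous runs of
#' super-threshold vertices are merged into a single cape placed at the
#' maximum-offset vertex of the run.
#'
#' @param coast high-resolution coastline (`x`, `y`).
#' @param smoothed smoothed coastline from [smooth_coastline()].
#' @param threshold designation threshold in km (default 5).
#' @return data frame of class `cape_set` with one row per cape:
#'   `x`, `y`, `s` (arc-length position on `coast`), `offset_km`. Zero
#'   rows when no excursion exceeds the threshold.
#' @export
detect_capes <- function(coast, smoothed, threshold = 5) {
  # window truncation leaves the smoothed polyline arc-shorter than the
  # coastline; extend it along its end tangents so offsets near the
  # domain ends measure deviation, not end-of-polyline distance
  n <- nrow(smoothed)
  d1 <- c(smoothed$x[1] - smoothed$x[2], smoothed$y[1] - smoothed$y[2])
  d2 <- c(smoothed$x[n] - smoothed$x[n - 1], smoothed$y[n] - smoothed$y[n - 1])
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  ext <- 10 * max(polyline_arclength(coast$x, coast$y))
  sx <- c(smoothed$x[1] + ext * d1[1], smoothed$x, smoothed$x[n] + ext * d2[1])
  sy <- c(smoothed$y[1] + ext * d1[2], smoothed$y, smoothed$y[n] + ext * d2[2])
  d <- dist_to_polyline(coast$x, coast$y, sx, sy)
  over <- d > threshold
  s <- polyline_arclength(coast$x, coast$y)
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    idx <- starts[i]:ends[i]
    j <- idx[which.max(d[idx])]
    rows[[length(rows) + 1L]] <- data.frame(
      x = coast$x[j], y = coast$y[j], s = s[j], offset_km = d[j])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), s = numeric(0),
               offset_km = numeric(0))
  class(out) <- c("cape_set", "data.frame")
  out
}

#' Signed distance to the nearest cape
#'
#' Euclidean distance to the nearest cape, negative for points north of
#' that cape (larger y / latitude) and positive for points south of it;
#' zero at the cape itself.
#'
#' @param x,y point coordinates in km (vectors).
#' @param capes a `cape_set` from [detect_capes()].
#' @return signed distances in km.
#' @export
distance_to_cape <- function(x, y, capes) {
  if (nrow(capes) == 0) stop("empty cape set: omit the cape covariate")
  d2 <- outer(x, capes$x, "-")^2 + outer(y, capes$y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  d <- sqrt(d2[cbind(seq_along(x), nearest)])
  sgn <- ifelse(y > capes$y[nearest], -1, 1)
  ifelse(d == 0, 0, sgn * d)
}

#' Shelf width per latitude row
#'
#' The shortest distance from the coast to the 200 m isobath at each
#' latitude row of a depth grid, with the crossing located by linear
#' interpolation between cell centres along the row. A single value per
#' row, broadcast across longitudes. Rows whose isobath lies outside the
#' grid get NA (flagged missing; such segments are dropped from model
#' fitting).
#'
#' @param grid grid frame with columns `x`, `y`, `depth` (m, NA on land).
#' @param coast coastline polyline (`x`, `y`) with y monotone.
#' @param isobath_m isobath depth in m (default 200).
#' @return data frame `y`, `shelf_width` (km) with one row per grid row.
#' @export
shelf_width <- function(grid, coast, isobath_m = 200) {
  ys <- sort(unique(grid$y))
  xc <- stats::approx(coast$y, coast$x, xout = ys, rule = 2)$y
  width <- rep(NA_real_, length(ys))
  for (i in seq_along(ys)) {
    row <- grid[grid$y == ys[i] & !is.na(grid$depth), ]
    if (nrow(row) < 2) next
    ord <- order(row$x)
    xs <- row$x[ord]; dep <- row$depth[ord]
    cross <- which(dep >= isobath_m)[1]
    if (is.na(cross)) next
    if (cross == 1) {
      x200 <- xs[1]
    } else {
      x0 <- xs[cross - 1]; x1 <- xs[cross]
      d0 <- dep[cross - 1]; d1 <- dep[cross]
      x200 <- x0 + (isobath_m - d0) / (d1 - d0) * (x1 - x0)
    }
    width[i] <- x200 - xc[i]
  }
  data.frame(y = ys, shelf_width = width)
}

#' Distance to the nearest qualifying estuary
#'
#' Euclidean distance to the nearest river estuary with area strictly
#' greater than `min_area_ha` (the covariate is limited to river
#' estuaries above 300 hectares, excluding small creeks).
#'
#' @param x,y point coordinates in km (vectors).
#' @param estuaries data frame `x`, `y`, `area_ha`.
#' @param min_area_ha area threshold in hectares (default 300).
#' @return distances in km.
#' @export
distance_to_estuary <- function(x, y, estuaries, min_area_ha = 300) {
  est <- estuaries[estuaries$area_ha > min_area_ha, , drop = FALSE]
  if (nrow(est) == 0) stop("no estuary exceeds ", min_area_ha, " hectares")
  d2 <- outer(x, est$x, "-")^2 + outer(y, est$y, "-")^2
  sqrt(apply(d2, 1, min))
}

#' Build the static covariate stack
#'
#' Computes all six static habitat layers on the world's 1 km grid:
#' depth, distance to coast, shelf width (one value per latitude row),
#' signed distance to cape (NA everywhere when no cape exceeds the
#' threshold), distance to estuary, and substrate. Land cells carry NA.
#'
#' @param world a `synthetic_world`, or any list with `coastline`, `grid`
#'   (with `depth` and `substrate`), `estuaries`, `config` (for the
#'   latitude mapping).
#' @param smooth_window coastline smoothing window in km (default 200).
#' @param cape_threshold cape designation threshold in km (default 5).
#' @param min_estuary_ha estuary area threshold (default 300).
#' @return a grid frame of class `static_stack` with columns `x`, `y`,
#'   `lat`, `lat_bin`, `depth`, `dist_coast`, `shelf_width`, `dist_cape`,
#'   `dist_estuary`, `substrate`; the detected `cape_set` and the
#'   smoothed coastline are attached as attributes `capes` and
#'   `smoothed_coastline`.
#' @export
rasterize_static <- function(world, smooth_window = 200, cape_threshold = 5,
                             min_estuary_ha = 300) {
  coast <- world$coastline
  grid <- world$grid
  cfg <- world$config
  stack <- grid
  sea <- !is.na(grid$depth)
  stack$lat <- y_to_lat(grid$y, cfg$lat0, cfg$km_per_degree)
  stack$lat_bin <- lat_bin_of(stack$lat)
  stack$dist_coast <- NA_real_
  stack$dist_coast[sea] <- dist_to_polyline(grid$x[sea], grid$y[sea],
                                            coast$x, coast$y)
  sw <- shelf_width(grid, coast)
  stack$shelf_width <- sw$shelf_width[match(grid$y, sw$y)]
  smoothed <- smooth_coastline(coast, smooth_window)
  capes <- detect_capes(coast, smoothed, cape_threshold)
  stack$dist_cape <- NA_real_
  if (nrow(capes) > 0) {
    stack$dist_cape[sea] <- distance_to_cape(grid$x[sea], grid$y[sea], capes)
  }
  stack$dist_estuary <- NA_real_
  stack$dist_estuary[sea] <- distance_to_estuary(grid$x[sea], grid$y[sea],
                                                 world$estuaries, min_estuary_ha)
  for (a in c("xmin", "ymin", "res", "nx", "ny")) {
    attr(stack, a) <- attr(grid, a)
  }
  attr(stack, "capes") <- capes
  attr(stack, "smoothed_coastline") <- smoothed
  class(stack) <- c("static_stack", "data.frame")
  stack
}

#' Extract static covariates at point locations
#'
#' Nearest-cell lookup of all static layers at the given coordinates.
#'
#' @param stack a `static_stack`.
#' @param x,y point coordinates in km.
#' @return data frame of static covariates, one row per point; NA rows
#'   for points on land or outside the grid.
#' @export
static_extract <- function(stack, x, y) {
  grid_extract(stack, x, y,
               c("depth", "dist_coast", "shelf_width", "dist_cape",
                 "dist_estuary", "substrate", "lat", "lat_bin"))
}
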