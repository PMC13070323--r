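# Line-transect survey simulation on the synthetic world, following the
# Marbled-Murrelet monitoring design: the coastline is partitioned into
# 20 km primary sampling units (PSUs); each sampled PSU yields four 5 km
# inshore segments parallel to the coast at independently randomised
# offsets (< 1.5 km from shore in the northern design region, < 2 km in
# the southern), plus one 5 km diagonal offshore transect from the
# inshore boundary out to the 5 km (north) or 3 km (south) offshore
# boundary with a randomised alongshore start.

#' Simulate survey effort
#'
#' Generates transect segments (effort only; see [simulate_sightings()]
#' for observations) for every PSU on every sampling occasion of every
#' year. Dates are drawn uniformly within the configured survey window,
#' and Beaufort sea state / sightability conditions are drawn per
#' segment from the configured categorical distributions.
#'
#' @param world a `synthetic_world`.
#' @param years integer vector of survey years (must be covered by the
#'   world's upwelling series).
#' @param occasions_per_year number of times each PSU is sampled per year
#'   (the historical design leaves this open; default 4).
#' @param seed integer seed.
#' @param psu_length_km PSU length in km (default 20).
#' @param segment_length_km inshore segment length in km (default 5).
#' @return data frame of class `survey_effort` with one row per segment:
#'   `segment_id`, `psu`, `year`, `occasion`, `date`, `type`
#'   ("inshore"/"offshore"), `offset_km`, endpoints `x0, y0, x1, y1`,
#'   centroid `cx, cy`, `length_km`, `bss`, `sightability`, `lat`,
#'   `lat_bin`.
#' @export
simulate_surveys <- function(world, years, occasions_per_year = 4, seed = 1,
                             psu_length_km = 20, segment_length_km = 5) {
  if (length(years) == 0) stop("years must be non-empty")
  if (psu_length_km <= 0) stop("psu_length_km must be positive")
  cfg <- world$config
  coast <- world$coastline
  total <- max(coast$s)
  if (total < psu_length_km) stop("coastline shorter than one PSU")
  set.seed(seed)
  n_psu <- ceiling(total / psu_length_km - 1e-9)
  psu_start <- (seq_len(n_psu) - 1) * psu_length_km
  psu_len <- pmin(psu_length_km, total - psu_start)

  boundary_lat <- cfg$design_boundary_lat
  rows <- list()
  seg_id <- 0L
  window_start <- cfg$survey_window[1]
  window_end <- cfg$survey_window[2]
  for (yr in years) {
    d0 <- as.Date(sprintf("%d-%s", yr, window_start))
    d1 <- as.Date(sprintf("%d-%s", yr, window_end))
    for (occ in seq_len(occasions_per_year)) {
      for (j in seq_len(n_psu)) {
        date <- d0 + floor(stats::runif(1, 0, as.numeric(d1 - d0) + 1))
        mid <- polyline_point_at(coast$x, coast$y, psu_start[j] + psu_len[j] / 2)
        psu_lat <- y_to_lat(mid$y, cfg$lat0, cfg$km_per_degree)
        south <- !is.na(boundary_lat) && psu_lat < boundary_lat
        max_off <- if (south) cfg$inshore_max_south_km else cfg$inshore_max_north_km
        outer_km <- if (south) cfg$offshore_limit_south_km else cfg$offshore_limit_north_km

        quarter <- psu_len[j] / 4
        offsets <- stats::runif(4, 0, max_off)
        for (q in 1:4) {
          s0 <- psu_start[j] + (q - 1) * quarter
          s1 <- s0 + min(segment_length_km, quarter)
          p0 <- polyline_point_at(coast$x, coast$y, s0)
          p1 <- polyline_point_at(coast$x, coast$y, s1)
          a <- c(p0$x + offsets[q] * p0$nx, p0$y + offsets[q] * p0$ny)
          b <- c(p1$x + offsets[q] * p1$nx, p1$y + offsets[q] * p1$ny)
          seg_id <- seg_id + 1L
          rows[[seg_id]] <- data.frame(
            segment_id = sprintf("S%06d", seg_id), psu = j, year = yr,
            occasion = occ, date = date, type = "inshore",
            offset_km = offsets[q],
            x0 = a[1], y0 = a[2], x1 = b[1], y1 = b[2],
            cx = (a[1] + b[1]) / 2, cy = (a[2] + b[2]) / 2,
            length_km = sqrt(sum((b - a)^2)),
            bss = as.numeric(sample(names(cfg$bss_probs), 1,
                                    prob = cfg$bss_probs)),
            sightability = as.numeric(sample(names(cfg$sightability_probs), 1,
                                             prob = cfg$sightability_probs)))
        }
        # diagonal offshore transect: fixed 5 km from the inshore
        # boundary (max_off) to the offshore boundary (outer_km)
        cross <- outer_km - max_off
        along <- sqrt(max(segment_length_km^2 - cross^2, 1))
        s_off <- psu_start[j] +
          stats::runif(1, 0, max(psu_len[j] - along, 1e-6))
        p0 <- polyline_point_at(coast$x, coast$y, s_off)
        p1 <- polyline_point_at(coast$x, coast$y, s_off + along)
        a <- c(p0$x + max_off * p0$nx, p0$y + max_off * p0$ny)
        b <- c(p1$x + outer_km * p1$nx, p1$y + outer_km * p1$ny)
        seg_id <- seg_id + 1L
        rows[[seg_id]] <- data.frame(
          segment_id = sprintf("S%06d", seg_id), psu = j, year = yr,
          occasion = occ, date = date, type = "offshore",
          offset_km = NA_real_,
          x0 = a[1], y0 = a[2], x1 = b[1], y1 = b[2],
          cx = (a[1] + b[1]) / 2, cy = (a[2] + b[2]) / 2,
          length_km = sqrt(sum((b - a)^2)),
          bss = as.numeric(sample(names(cfg$bss_probs), 1,
                                  prob = cfg$bss_probs)),
          sightability = as.numeric(sample(names(cfg$sightability_probs), 1,
                                           prob = cfg$sightability_probs)))
      }
    }
  }
  effort <- do.call(rbind, rows)
  effort$lat <- y_to_lat(effort$cy, cfg$lat0, cfg$km_per_degree)
  effort$lat_bin <- lat_bin_of(effort$lat)
  class(effort) <- c("survey_effort", "data.frame")
  effort
}

#' Simulate sightings along surveyed segments
#'
#' Places porpoise groups by an inhomogeneous Poisson process with the
#' world's true group-density surface (groups/km^2, evaluated at the
#' segment centroid covariates on the segment date), draws perpendicular
#' distances uniformly within the simulation strip, and retains each
#' group with probability `g(x)` under the true detection function,
#' whose scale may depend on the segment's Beaufort sea state and
#' sightability. Group sizes are zero-truncated Poisson.
#'
#' @param world a `synthetic_world`.
#' @param effort a `survey_effort` from [simulate_surveys()].
#' @param seed integer seed.
#' @param daily_state optional precomputed [daily_upwelling_state()]
#'   table (computed from the world's upwelling series when NULL).
#' @return data frame of class `survey_sightings` with one row per
#'   detected group: `segment_id`, `date`, `year`, `distance_m`, `size`,
#'   `bss`, `sightability`.
#' @export
simulate_sightings <- function(world, effort, seed = 1, daily_state = NULL) {
  set.seed(seed)
  cfg <- world$config
  det <- world$truth$detection
  w_sim <- cfg$w_sim_m
  if (is.null(daily_state)) {
    phen <- upwelling_phenology(world$cuti)
    daily_state <- daily_upwelling_state(world$cuti, phen)
  }
  depth <- grid_extract(world$grid, effort$cx, effort$cy, "depth")$depth
  key <- paste(effort$date, effort$lat_bin)
  dkey <- paste(daily_state$date, daily_state$lat_bin)
  cum <- daily_state$cumulative_cuti[match(key, dkey)]
  covars <- data.frame(depth = depth, cumulative_cuti = cum)
  dens <- world$truth$density(covars)
  dens[is.na(dens)] <- 0
  if (any(dens < 0)) stop("true density must be non-negative")

  sigma <- exp(log(det$sigma0_m) + det$beta_bss * effort$bss +
                 det$beta_sightability * effort$sightability)
  area_km2 <- effort$length_km * 2 * (w_sim / 1000)
  n_groups <- stats::rpois(nrow(effort), dens * area_km2)
  rows <- vector("list", nrow(effort))
  for (i in which(n_groups > 0)) {
    xs <- stats::runif(n_groups[i], 0, w_sim)
    keep <- stats::runif(n_groups[i]) <
      detection_g(xs, sigma[i], det$key, det$shape_b)
    if (!any(keep)) next
    xs <- xs[keep]
    rows[[i]] <- data.frame(
      segment_id = effort$segment_id[i], date = effort$date[i],
      year = effort$year[i], distance_m = xs,
      size = rztpois(length(xs), world$truth$group_size_lambda),
      bss = effort$bss[i], sightability = effort$sightability[i])
  }
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment_id = character(0), date = as.Date(character(0)),
               year = integer(0), distance_m = numeric(0), size = integer(0),
               bss = numeric(0), sightability = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("survey_sightings", "data.frame")
  out
}
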