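# Synthetic coastal world generator.
#
# The generator produces a seeded stand-in for the Northern California
# Current study system: a north-south coastline with promontories, a
# linearly sloping shelf, river estuaries, a binary substrate mosaic,
# daily upwelling-index (CUTI-like) series per 1-degree latitude bin,
# daily SST per bin, and a known detection function and group-density
# surface so that every downstream stage has a recovery test.

#' Configuration for the synthetic coastal world
#'
#' Returns the default world configuration, optionally overriding any
#' entry. Defaults emulate the study system: a nearly straight,
#' north-south coastline broken by prominent capes, a shelf whose 200 m
#' isobath sits 10-20 km offshore, estuaries of a few hundred to a few
#' thousand hectares, and a seasonal upwelling index that turns positive
#' at the spring transition (around day 100) and collapses in autumn
#' (around day 280).
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list with entries:
#' \describe{
#'   \item{coast_length_km}{alongshore extent of the domain (km).}
#'   \item{vertex_spacing_km}{coastline vertex spacing (km).}
#'   \item{lat0, km_per_degree}{linear northing-to-latitude mapping.}
#'   \item{offshore_extent_km, resolution_km}{bathymetry grid extent and
#'     resolution (1 km, the resolution of the static covariate stack).}
#'   \item{n_promontories, promontory_amplitude_km, promontory_width_km}{cape
#'     geometry: number, seaward excursion, and alongshore scale of
#'     Gaussian promontories.}
#'   \item{shelf_slope_m_per_km, slope_variation}{linear depth slope and its
#'     relative alongshore modulation (varies shelf width by latitude).}
#'   \item{n_estuaries, estuary_meanlog, estuary_sdlog}{estuary count and
#'     log-normal area distribution (hectares).}
#'   \item{cuti_winter, cuti_amplitude, cuti_amplitude_sd, sti_mean_doy,
#'     sti_sd, end_mean_doy, end_sd, cuti_ramp_days, cuti_ramp_down_days,
#'     cuti_ar, cuti_noise_sd}{upwelling-series shape: winter baseline and
#'     summer amplitude (m^2/s), year-to-year spread of onset/collapse
#'     days, spring and (sharper) fall ramp lengths, and AR(1) daily
#'     noise.}
#'   \item{sst_mean, sst_seasonal_amp, sst_upwelling_coef, sst_lat_coef,
#'     sst_noise_sd}{SST model (deg C): seasonal cycle, cooling per unit of
#'     smoothed upwelling index, latitudinal gradient, daily noise.}
#'   \item{detection}{true detection function: key ("hn" or "hr"),
#'     sigma0_m (scale at baseline conditions), beta_bss and
#'     beta_sightability (log-scale effects of conditions), shape_b
#'     (hazard-rate only).}
#'   \item{w_sim_m}{half-width of the strip in which groups are placed
#'     before detection thinning (m).}
#'   \item{group_size_mean}{mean of the zero-truncated Poisson group-size
#'     distribution (1.46 individuals per group).}
#'   \item{density_baseline_groups_km2, density_depth_opt_m,
#'     density_depth_scale_m, density_cuti_coef}{true group-density surface:
#'     log-quadratic in depth around an optimum, log-linear in cumulative
#'     smoothed upwelling since the spring transition.}
#'   \item{bss_probs, sightability_probs}{marginal distributions of Beaufort
#'     sea state (0-5) and ordinal sightability (1-5) per segment.}
#'   \item{inshore_max_north_km, inshore_max_south_km, offshore_limit_north_km,
#'     offshore_limit_south_km, design_boundary_lat}{survey design: maximum
#'     random inshore offsets and offshore-transect outer boundaries for the
#'     northern and southern design regions, and the latitude separating
#'     them (NA = northern design everywhere).}
#'   \item{survey_window}{month-day start and end of the field season.}
#' }
#' @export
world_config <- function(...) {
  cfg <- list(
    coast_length_km = 400,
    vertex_spacing_km = 0.5,
    lat0 = 40,
    km_per_degree = 111,
    offshore_extent_km = 24,
    resolution_km = 1,
    n_promontories = 3,
    promontory_amplitude_km = 8,
    promontory_width_km = 30,
    shelf_slope_m_per_km = 15,
    slope_variation = 0.3,
    n_estuaries = 6,
    estuary_meanlog = log(500),
    estuary_sdlog = 0.9,
    cuti_winter = -0.4,
    cuti_amplitude = 1.2,
    cuti_amplitude_sd = 0.05,
    sti_mean_doy = 100,
    sti_sd = 18,
    end_mean_doy = 280,
    end_sd = 5,
    cuti_ramp_days = 20,
    cuti_ramp_down_days = 8,
    cuti_ar = 0.6,
    cuti_noise_sd = 0.25,
    sst_mean = 13,
    sst_seasonal_amp = 3,
    sst_upwelling_coef = -1.5,
    sst_lat_coef = -0.4,
    sst_noise_sd = 0.3,
    detection = list(key = "hn", sigma0_m = 100,
                     beta_bss = 0, beta_sightability = 0, shape_b = 2.5),
    w_sim_m = 400,
    group_size_mean = 1.46,
    density_baseline_groups_km2 = 0.6,
    density_depth_opt_m = 15,
    density_depth_scale_m = 45,
    density_cuti_coef = 0.008,
    bss_probs = c(`0` = 0.05, `1` = 0.20, `2` = 0.30,
                  `3` = 0.25, `4` = 0.15, `5` = 0.05),
    sightability_probs = c(`1` = 0.05, `2` = 0.15, `3` = 0.30,
                           `4` = 0.30, `5` = 0.20),
    inshore_max_north_km = 1.5,
    inshore_max_south_km = 2.0,
    offshore_limit_north_km = 5,
    offshore_limit_south_km = 3,
    design_boundary_lat = NA_real_,
    survey_window = c("05-15", "08-30")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown world_config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

# mean of a zero-truncated Poisson is lambda / (1 - exp(-lambda));
# invert numerically for the configured mean group size.
ztpois_lambda <- function(mean_size) {
  if (mean_size <= 1) stop("mean group size must exceed 1")
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean_size,
                 c(1e-8, 4 * mean_size))$root
}

rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# seasonal smoothstep: cosine taper up over 2*ramp_up days around the
# onset and down over 2*ramp_down days around the collapse (the fall
# transition of upwelling systems is much more abrupt than the spring one)
season_taper <- function(doy, on, off, ramp_up, ramp_down = ramp_up) {
  up <- pmin(pmax((doy - (on - ramp_up)) / (2 * ramp_up), 0), 1)
  dn <- pmin(pmax(((off + ramp_down) - doy) / (2 * ramp_down), 0), 1)
  (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * dn))
}

generate_cuti <- function(cfg, years, bins) {
  out <- vector("list", length(years) * length(bins))
  k <- 0L
  for (yr in years) {
    dates <- seq(as.Date(sprintf("%d-01-01", yr)), as.Date(sprintf("%d-12-31", yr)), by = "day")
    doy <- seq_along(dates)
    sti_y <- stats::rnorm(1, cfg$sti_mean_doy, cfg$sti_sd)
    end_y <- stats::rnorm(1, cfg$end_mean_doy, cfg$end_sd)
    amp_y <- max(stats::rnorm(1, cfg$cuti_amplitude, cfg$cuti_amplitude_sd), 0.3)
    for (b in seq_along(bins)) {
      amp_b <- amp_y * (1 - 0.05 * (b - 1))
      base <- cfg$cuti_winter +
        (amp_b - cfg$cuti_winter) *
        season_taper(doy, sti_y, end_y, cfg$cuti_ramp_days, cfg$cuti_ramp_down_days)
      innov <- stats::rnorm(length(doy), 0, cfg$cuti_noise_sd)
      noise <- as.numeric(stats::filter(innov, cfg$cuti_ar, method = "recursive"))
      k <- k + 1L
      out[[k]] <- data.frame(date = dates, year = yr, lat_bin = bins[b],
                             cuti = base + noise)
    }
  }
  do.call(rbind, out)
}

generate_sst <- function(cfg, cuti) {
  doy <- as.POSIXlt(cuti$date)$yday + 1
  sm <- numeric(nrow(cuti))
  for (g in split(seq_len(nrow(cuti)), list(cuti$lat_bin, cuti$year), drop = TRUE)) {
    sm[g] <- smooth_cuti(cuti$cuti[g])
  }
  seasonal <- cfg$sst_seasonal_amp * sin(2 * pi * (doy - 110) / 365)
  sst <- cfg$sst_mean + seasonal +
    cfg$sst_upwelling_coef * sm +
    cfg$sst_lat_coef * (cuti$lat_bin - cfg$lat0) +
    stats::rnorm(nrow(cuti), 0, cfg$sst_noise_sd)
  data.frame(date = cuti$date, year = cuti$year, lat_bin = cuti$lat_bin, sst = sst)
}

#' Generate a seeded synthetic coastal world
#'
#' Builds a complete synthetic study system from a configuration and a
#' seed: coastline polyline, 1 km bathymetry and substrate grids,
#' estuaries, daily upwelling-index series per 1-degree latitude bin for
#' the requested years, daily SST per bin, and the true detection and
#' group-density model used by [simulate_sightings()]. Identical
#' configuration and seed give a bitwise-identical world.
#'
#' @param config a list from [world_config()].
#' @param seed integer seed controlling every random element.
#' @param years integer vector of calendar years to cover with daily
#'   upwelling and SST series.
#'
#' @return An object of class `synthetic_world`: a list with elements
#'   `coastline` (data frame `x`, `y`, `s` arc length, ordered south to
#'   north; the sea is the +x side), `grid` (grid frame with `depth` in m,
#'   positive down, NA on land, and `substrate` in {"hard","soft"}),
#'   `estuaries` (`x`, `y`, `area_ha`), `cuti` (`date`, `year`, `lat_bin`,
#'   `cuti` in m^2/s), `sst` (`date`, `year`, `lat_bin`, `sst` in deg C),
#'   `truth` (detection parameters, group-size rate, and the group-density
#'   function of covariates), `config`, `seed`, `years`.
#' @export
generate_world <- function(config = world_config(), seed = 1,
                           years = 2001:2005) {
  cfg <- config
  if (cfg$coast_length_km <= 0 || cfg$resolution_km <= 0 ||
      cfg$offshore_extent_km <= 0) {
    stop("domain extent and resolution must be positive")
  }
  set.seed(seed)

  # coastline: x = f(y), promontories are seaward Gaussian bumps
  yv <- seq(0, cfg$coast_length_km, by = cfg$vertex_spacing_km)
  xc <- rep(0, length(yv))
  promontories <- data.frame(y = numeric(0), amplitude = numeric(0))
  if (cfg$n_promontories > 0) {
    centres <- seq(0.15, 0.85, length.out = cfg$n_promontories) * cfg$coast_length_km
    centres <- centres + stats::runif(cfg$n_promontories, -10, 10)
    sdw <- cfg$promontory_width_km / 4
    for (cy in centres) xc <- xc + cfg$promontory_amplitude_km * exp(-((yv - cy) / sdw)^2)
    promontories <- data.frame(y = centres, amplitude = cfg$promontory_amplitude_km)
  }
  coastline <- data.frame(x = xc, y = yv)
  coastline$s <- polyline_arclength(coastline$x, coastline$y)

  # bathymetry + substrate on a common 1 km grid
  grid <- make_grid_frame(min(xc), max(xc) + cfg$offshore_extent_km,
                          0, cfg$coast_length_km, cfg$resolution_km)
  xc_at <- stats::approx(yv, xc, xout = grid$y, rule = 2)$y
  slope <- cfg$shelf_slope_m_per_km *
    (1 + cfg$slope_variation * sin(2 * pi * grid$y / cfg$coast_length_km))
  offshore <- grid$x - xc_at
  grid$depth <- ifelse(offshore >= 0, slope * offshore, NA_real_)
  bump <- xc_at  # promontory excursion at this latitude
  speckle <- stats::runif(nrow(grid))
  grid$substrate <- ifelse(!is.na(grid$depth) &
                             (bump > 0.25 * max(cfg$promontory_amplitude_km, 1) |
                              speckle < 0.10),
                           "hard", "soft")
  grid$substrate[is.na(grid$depth)] <- NA_character_

  # estuaries on the coastline
  ey <- sort(stats::runif(cfg$n_estuaries, 0, cfg$coast_length_km))
  estuaries <- data.frame(
    x = stats::approx(yv, xc, xout = ey, rule = 2)$y,
    y = ey,
    area_ha = stats::rlnorm(cfg$n_estuaries, cfg$estuary_meanlog, cfg$estuary_sdlog)
  )

  bins <- sort(unique(lat_bin_of(y_to_lat(c(0, cfg$coast_length_km), cfg$lat0,
                                          cfg$km_per_degree))))
  bins <- seq(min(bins), max(bins))
  cuti <- generate_cuti(cfg, years, bins)
  sst <- generate_sst(cfg, cuti)

  lambda <- ztpois_lambda(cfg$group_size_mean)
  dens_cfg <- cfg[c("density_baseline_groups_km2", "density_depth_opt_m",
                    "density_depth_scale_m", "density_cuti_coef")]
  density_fun <- function(covars) {
    d <- covars$depth
    cc <- covars$cumulative_cuti
    if (is.null(cc)) cc <- 0
    logd <- log(dens_cfg$density_baseline_groups_km2) -
      ((d - dens_cfg$density_depth_opt_m) / dens_cfg$density_depth_scale_m)^2 +
      dens_cfg$density_cuti_coef * cc
    exp(logd)
  }

  structure(list(
    coastline = coastline,
    grid = grid,
    estuaries = estuaries,
    promontories = promontories,
    cuti = cuti,
    sst = sst,
    truth = list(detection = cfg$detection,
                 group_size_lambda = lambda,
                 density = density_fun),
    config = cfg,
    seed = seed,
    years = years
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_world>\n")
  cat(sprintf("  coastline: %.0f km (%d vertices), %d promontories\n",
              max(x$coastline$s), nrow(x$coastline), nrow(x$promontories)))
  cat(sprintf("  grid: %d cells at %.0f km; estuaries: %d\n",
              nrow(x$grid), cfg$resolution_km, nrow(x$estuaries)))
  cat(sprintf("  upwelling series: %d lat bins x years %s\n",
              length(unique(x$cuti$lat_bin)),
              paste(range(x$years), collapse = "-")))
  invisible(x)
}
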