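# End-to-end simulation study: synthetic world -> surveys -> detection
# -> segments -> density surface models -> filtered daily predictions
# -> annual anomalies -> phenology trend models.

#' Run the full pipeline on a synthetic world
#'
#' Generates a seeded world and surveys, fits the detection function
#' and per-stock density surface models, predicts daily density over
#' the coastal grid with ExDet day filtering, summarizes annual density
#' anomalies, and regresses the anomalies on the upwelling-phenology
#' indices (and, optionally, user-supplied climate indices). Defaults
#' run at a reduced desk scale (5 years, two stocks on a 200 km coast)
#' that exercises every stage.
#'
#' @param seed integer seed; every random stage derives its own seed
#'   from it.
#' @param years survey years (default 2001:2005).
#' @param config world configuration (default: [world_config()] with a
#'   200 km coast and two promontories).
#' @param stocks named list of stock latitude ranges (default: two
#'   stocks splitting the coast).
#' @param occasions_per_year PSU sampling occasions per year (default 4).
#' @param detection_key,detection_covariates detection model to fit
#'   (default: the world's generating half-normal, covariate-free).
#' @param drop_cape_for optional stock labels whose DSM omits the cape
#'   covariate.
#' @return list with `world`, `effort`, `sightings`, `truncation`,
#'   `detection`, `static`, `phenology`, `daily_state`, `segments`,
#'   `fits` (per stock), `grid`, `predictions` (per stock), `summary`
#'   (cell/daily/annual), `regressors`, `trends` (per phenology index).
#' @export
simulate_study <- function(seed = 1, years = 2001:2005, config = NULL,
                           stocks = NULL, occasions_per_year = 4,
                           detection_key = "hn",
                           detection_covariates = character(),
                           drop_cape_for = character()) {
  if (is.null(config)) {
    config <- world_config(coast_length_km = 200, n_promontories = 2)
  }
  lat_lo <- config$lat0
  lat_hi <- config$lat0 + config$coast_length_km / config$km_per_degree
  if (is.null(stocks)) {
    mid <- (lat_lo + lat_hi) / 2
    stocks <- list(south = c(lat_lo, mid), north = c(mid, lat_hi))
  }
  world <- generate_world(config, seed = seed, years = years)
  effort <- simulate_surveys(world, years = years,
                             occasions_per_year = occasions_per_year,
                             seed = seed + 1000L)
  phen <- upwelling_phenology(world$cuti)
  daily <- daily_upwelling_state(world$cuti, phen)
  sightings <- simulate_sightings(world, effort, seed = seed + 2000L,
                                  daily_state = daily)

  tr <- truncate_distances(sightings$distance_m)
  detfit <- fit_detection(sightings[tr$keep, ], key = detection_key,
                          covariates = detection_covariates, w = tr$w)
  static <- rasterize_static(world)
  segments <- build_segments(effort, sightings, static, daily, world$sst,
                             detfit, stocks)
  grid <- prediction_grid(world, static, stocks)

  fits <- list(); preds <- list()
  for (st in names(stocks)) {
    drop <- if (st %in% drop_cape_for ||
                nrow(attr(static, "capes")) == 0) "dist_cape" else NULL
    fits[[st]] <- fit_dsm(segments, stock = st, drop_terms = drop)
    preds[[st]] <- predict_surface(fits[[st]], grid[grid$stock == st, ],
                                   daily, world$sst, years)
  }
  all_pred <- do.call(rbind, lapply(preds, `[[`, "predictions"))
  summ <- summarize_predictions(all_pred)

  sm <- stock_phenology_means(phen, stocks)
  reg <- phenology_regressors(sm)
  trend_data <- merge(summ$annual, reg, by = c("stock", "year"))
  trends <- list()
  for (idx in c("sti", "max_day", "tumi", "lusi")) {
    td <- data.frame(anomaly = trend_data$anomaly,
                     index = trend_data[[idx]],
                     stock = trend_data$stock)
    trends[[idx]] <- tryCatch(fit_trend(td, index_name = idx),
                              error = function(e) NULL)
  }

  list(world = world, effort = effort, sightings = sightings,
       truncation = tr, detection = detfit, static = static,
       phenology = phen, daily_state = daily, segments = segments,
       fits = fits, grid = grid, predictions = preds, summary = summ,
       regressors = reg, trends = trends)
}
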