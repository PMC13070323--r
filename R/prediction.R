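# Daily prediction over a 5 km coastal grid, ExDet extrapolation
# filtering of non-analog days, long-term hotspot summaries, annual
# density series with uncertainty, and standardized density anomalies.

#' Build the coastal prediction grid
#'
#' Cells of `cell_km` alongshore extent spanning the strip between the
#' coastline and `offshore_km` offshore. Cell centres sit at half the
#' strip width seaward of the coast; the alongshore extent of the last
#' cell is truncated at the end of the coastline and the cell area is
#' the exact alongshore x cross-shore product.
#'
#' @param world a `synthetic_world`.
#' @param static a `static_stack` (for covariates at cell centres).
#' @param stocks named list of stock latitude ranges.
#' @param cell_km alongshore cell size in km (default 5).
#' @param offshore_km offshore extent of the strip in km (default 5).
#' @return data frame of class `prediction_grid`: `cell_id`, `x`, `y`,
#'   `lat`, `lat_bin`, `area_km2`, static covariates, `stock`.
#' @export
prediction_grid <- function(world, static, stocks, cell_km = 5,
                            offshore_km = 5) {
  coast <- world$coastline
  cfg <- world$config
  total <- max(coast$s)
  starts <- seq(0, total - 1e-9, by = cell_km)
  len <- pmin(cell_km, total - starts)
  mid <- polyline_point_at(coast$x, coast$y, starts + len / 2)
  cx <- mid$x + (offshore_km / 2) * mid$nx
  cy <- mid$y + (offshore_km / 2) * mid$ny
  g <- data.frame(cell_id = seq_along(starts), x = cx, y = cy,
                  lat = y_to_lat(cy, cfg$lat0, cfg$km_per_degree),
                  area_km2 = len * offshore_km)
  g$lat_bin <- lat_bin_of(g$lat)
  st <- static_extract(static, g$x, g$y)
  g$depth <- st$depth
  g$dist_coast <- st$dist_coast
  g$shelf_width <- st$shelf_width
  g$dist_cape <- st$dist_cape
  g$dist_estuary <- st$dist_estuary
  g$substrate <- st$substrate
  g$stock <- assign_stock(g$lat, stocks)
  complete <- stats::complete.cases(
    g[c("depth", "dist_coast", "shelf_width", "dist_estuary", "substrate")])
  if (any(!complete)) {
    warning(sum(!complete), " grid cell(s) dropped for missing covariates")
    g <- g[complete, ]
  }
  class(g) <- c("prediction_grid", "data.frame")
  g
}

#' ExDet extrapolation statistic
#'
#' Univariate (NT1) and combinatorial (NT2) extrapolation detection.
#' For each point, `UD_j = min(x_j - min_j, max_j - x_j, 0) / (max_j -
#' min_j)` over the reference range of each covariate and `NT1 = sum_j
#' UD_j`; a negative NT1 (range extrapolation) is returned directly.
#' Otherwise the statistic is `NT2`, the squared Mahalanobis distance of
#' the point from the reference mean divided by the maximum squared
#' Mahalanobis distance among the reference points, so analog conditions
#' fall in [0, 1] and NT2 > 1 flags novel covariate combinations.
#'
#' @param reference matrix or data frame of reference covariate rows
#'   (the conditions used to fit the model).
#' @param points matrix or data frame of covariate rows to score (same
#'   columns).
#' @return numeric vector of ExDet values, one per row of `points`.
#' @export
exdet <- function(reference, points) {
  ref <- as.matrix(reference)
  pts <- as.matrix(points[, colnames(ref), drop = FALSE])
  if (nrow(ref) < 2) stop("reference must have at least 2 rows")
  lo <- apply(ref, 2, min); hi <- apply(ref, 2, max)
  span <- hi - lo
  if (any(span == 0)) stop("zero reference range for: ",
                           paste(colnames(ref)[span == 0], collapse = ", "))
  lo_m <- matrix(lo, nrow(pts), ncol(pts), byrow = TRUE)
  hi_m <- matrix(hi, nrow(pts), ncol(pts), byrow = TRUE)
  span_m <- matrix(span, nrow(pts), ncol(pts), byrow = TRUE)
  ud <- pmin(pts - lo_m, hi_m - pts, 0) / span_m
  nt1 <- rowSums(ud)
  mu <- colMeans(ref)
  S <- stats::cov(ref)
  d2 <- stats::mahalanobis(pts, mu, S)
  d2max <- max(stats::mahalanobis(ref, mu, S))
  unname(ifelse(nt1 < 0, nt1, d2 / d2max))
}

#' Flag prediction days with non-analog dynamic conditions
#'
#' Applies [exdet()] to the dynamic covariates of every prediction cell
#' and drops a day when any of its cells scores above `hi` or below
#' `lo`.
#'
#' @param day_covs data frame with a `date` column and the dynamic
#'   covariate columns of `reference`.
#' @param reference reference covariate rows (the fitting segments'
#'   dynamic covariates).
#' @param hi,lo thresholds (defaults 1.15 and -0.15).
#' @return list with `values` (the input plus an `exdet` column) and
#'   `days` (data frame `date`, `keep`).
#' @export
filter_days <- function(day_covs, reference, hi = 1.15, lo = -0.15) {
  vals <- exdet(reference, day_covs)
  out <- day_covs
  out$exdet <- vals
  bad <- vals > hi | vals < lo
  days <- stats::aggregate(list(drop = bad), by = list(date = day_covs$date),
                           FUN = any)
  data.frame(date = days$date, keep = !days$drop) -> days
  list(values = out, days = days)
}

#' Predict per-cell abundance and density
#'
#' Evaluates the fitted model on prediction rows carrying the cell area
#' as the offset: abundance is `area * exp(eta)` and density is
#' abundance per km^2.
#'
#' @param fit a `dsm_fit`.
#' @param newdata prediction rows with all model covariates and
#'   `area_km2`.
#' @return `newdata` with `abundance` and `density` columns appended.
#' @export
predict_density <- function(fit, newdata) {
  nd <- as.data.frame(newdata)
  nd$offset_area <- nd$area_km2
  if (!is.null(nd$substrate)) {
    nd$substrate <- factor(nd$substrate, levels = c("soft", "hard"))
  }
  nd$abundance <- as.numeric(stats::predict(fit$gam, newdata = nd,
                                            type = "response"))
  nd$density <- nd$abundance / nd$area_km2
  nd
}

window_dates <- function(years, window = c("05-15", "08-30")) {
  do.call(c, lapply(years, function(y) {
    seq(as.Date(sprintf("%d-%s", y, window[1])),
        as.Date(sprintf("%d-%s", y, window[2])), by = "day")
  }))
}

#' Daily density predictions over the survey season
#'
#' Expands the prediction grid over every day of the prediction window
#' (15 May - 30 August by default, endpoints inclusive) for the given
#' years, attaches the dynamic covariates by date and latitude bin,
#' scores every day with ExDet against the fit's training dynamic
#' conditions, and predicts abundance and density for all days (the
#' retained-day flag is carried alongside so summaries can exclude
#' non-analog days).
#'
#' @param fit a `dsm_fit` (one stock).
#' @param grid the stock's rows of a `prediction_grid`.
#' @param daily_state a [daily_upwelling_state()] table.
#' @param sst data frame `date`, `lat_bin`, `sst`.
#' @param years years to predict.
#' @param window month-day start and end of the prediction window.
#' @param exdet_lo,exdet_hi day-exclusion thresholds.
#' @return list with `predictions` (date, cell, covariates, abundance,
#'   density, exdet, keep) and `days` (date, keep).
#' @export
predict_surface <- function(fit, grid, daily_state, sst, years,
                            window = c("05-15", "08-30"),
                            exdet_lo = -0.15, exdet_hi = 1.15) {
  dates <- window_dates(years, window)
  nd <- grid[rep(seq_len(nrow(grid)), times = length(dates)), ]
  nd$date <- rep(dates, each = nrow(grid))
  key <- paste(nd$date, nd$lat_bin)
  dk <- paste(daily_state$date, daily_state$lat_bin)
  nd$cumulative_cuti <- daily_state$cumulative_cuti[match(key, dk)]
  nd$cumulative_relaxation <- daily_state$cumulative_relaxation[match(key, dk)]
  sk <- paste(sst$date, sst$lat_bin)
  nd$sst <- sst$sst[match(key, sk)]
  fd <- filter_days(nd[c("date", "cumulative_cuti", "cumulative_relaxation",
                         "sst")],
                    fit$reference_dynamic, hi = exdet_hi, lo = exdet_lo)
  nd$exdet <- fd$values$exdet
  nd$keep <- fd$days$keep[match(nd$date, fd$days$date)]
  pred <- predict_density(fit, nd)
  pred$year <- as.integer(format(pred$date, "%Y"))
  list(predictions = pred, days = fd$days)
}

#' Standardized density anomaly
#'
#' Centres a series of annual densities on its long-term mean and
#' divides by the sample standard deviation, expressing each year in
#' standard deviations from the mean.
#'
#' @param x numeric vector of annual mean densities (one stock).
#' @return z-scores with sample mean 0 and sample SD 1.
#' @export
density_anomaly <- function(x) {
  if (length(x) < 2) stop("need at least 2 years for an anomaly")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance: anomaly undefined")
  (x - mean(x)) / s
}

#' Summarize daily predictions into hotspots and annual series
#'
#' From the retained (analog) days only: per-cell long-term mean
#' abundance and density with a between-day CV; per-day study-area
#' abundance and density (sum over cells); and per-year mean daily
#' abundance and density with the standardized per-stock density
#' anomaly. Years with no retained day are emitted as missing.
#'
#' @param pred the `predictions` element of [predict_surface()] (may
#'   combine several stocks).
#' @return list with `cell_means`, `daily`, `annual`.
#' @export
summarize_predictions <- function(pred) {
  kept <- pred[pred$keep, ]
  if (nrow(kept) == 0) stop("no retained prediction days")
  cell <- stats::aggregate(
    cbind(mean_abundance = kept$abundance, mean_density = kept$density),
    by = list(stock = kept$stock, cell_id = kept$cell_id), FUN = mean)
  cell_sd <- stats::aggregate(list(sd_abundance = kept$abundance),
    by = list(stock = kept$stock, cell_id = kept$cell_id), FUN = stats::sd)
  cell$cv_between_days <- cell_sd$sd_abundance / cell$mean_abundance
  daily <- stats::aggregate(
    cbind(abundance = kept$abundance, area = kept$area_km2),
    by = list(stock = kept$stock, year = kept$year, date = kept$date),
    FUN = sum)
  daily$density <- daily$abundance / daily$area
  annual <- stats::aggregate(
    cbind(mean_abundance = daily$abundance, mean_density = daily$density),
    by = list(stock = daily$stock, year = daily$year), FUN = mean)
  all_years <- expand.grid(stock = unique(pred$stock),
                           year = sort(unique(pred$year)),
                           stringsAsFactors = FALSE)
  annual <- merge(all_years, annual, by = c("stock", "year"), all.x = TRUE)
  annual$anomaly <- NA_real_
  for (st in unique(annual$stock)) {
    sel <- annual$stock == st & !is.na(annual$mean_density)
    if (sum(sel) >= 2) {
      annual$anomaly[sel] <- density_anomaly(annual$mean_density[sel])
    }
  }
  annual <- annual[order(annual$stock, annual$year), ]
  rownames(annual) <- NULL
  list(cell_means = cell, daily = daily, annual = annual)
}

# multivariate normal draws via eigen decomposition; tolerates
# rank-deficient and all-zero covariance matrices
rmvn_eig <- function(n, mu, V) {
  p <- length(mu)
  ev <- eigen(V, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), p)
  t(mu + A %*% matrix(stats::rnorm(n * p), p, n))
}

#' Prediction uncertainty by coefficient simulation
#'
#' Draws coefficient vectors from the fitted model's asymptotic
#' sampling distribution, re-predicts, and reports the coefficient of
#' variation (SD / mean) per cell and per group total (e.g. per day).
#' Detection-function uncertainty is not propagated.
#'
#' @param fit a `dsm_fit`.
#' @param newdata prediction rows with covariates and `area_km2`.
#' @param group optional grouping vector (e.g. dates) for total-CV
#'   summaries; default: one group.
#' @param n_draws number of coefficient draws (default 200).
#' @param seed integer seed.
#' @return list with `cell_cv` (per row of `newdata`) and `group_cv`
#'   (data frame `group`, `cv`).
#' @export
prediction_cv <- function(fit, newdata, group = NULL, n_draws = 200, seed = 1) {
  set.seed(seed)
  nd <- as.data.frame(newdata)
  nd$offset_area <- nd$area_km2
  if (!is.null(nd$substrate)) {
    nd$substrate <- factor(nd$substrate, levels = c("soft", "hard"))
  }
  Xp <- stats::predict(fit$gam, newdata = nd, type = "lpmatrix")
  V <- stats::vcov(fit$gam)
  betas <- rmvn_eig(n_draws, as.numeric(stats::coef(fit$gam)), V)
  eta <- Xp %*% t(betas) + log(nd$area_km2)
  mu <- exp(eta)  # abundance per draw (columns)
  cell_cv <- apply(mu, 1, stats::sd) / rowMeans(mu)
  if (is.null(group)) group <- rep(1L, nrow(nd))
  tot <- rowsum(mu, group)
  gcv <- apply(tot, 1, stats::sd) / rowMeans(tot)
  list(cell_cv = cell_cv,
       group_cv = data.frame(group = rownames(tot), cv = gcv))
}
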