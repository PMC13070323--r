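# Upwelling phenology and dynamic covariates from daily coastal
# upwelling transport index (CUTI-like) series per 1-degree latitude bin.
#
# The conventions follow the cumulative-upwelling phenology of eastern
# boundary currents: smooth the daily index with a 10-day running mean,
# accumulate it from 1 January, take the day of the cumulative minimum as
# the spring transition (STI) and the day of the cumulative maximum as
# the season end (END, also reported as MAX), and derive TUMI (total
# in-season cumulative upwelling) and LUSI (season length in days).
# Relaxation events are in-season days on which the smoothed index falls
# below its long-term in-season mean for that latitude bin.

#' Running-mean smoother for a daily upwelling series
#'
#' Centred running mean; near the edges the mean is taken over the
#' available sub-window. For an even window length the centre is placed
#' so that the window reaches `floor((window-1)/2)` days back and
#' `ceiling((window-1)/2)` days forward.
#'
#' @param x numeric daily series.
#' @param window window length in days (default 10).
#' @return numeric vector of the same length.
#' @export
smooth_cuti <- function(x, window = 10) {
  if (length(x) == 0) stop("empty series")
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  back <- floor((window - 1) / 2)
  fwd <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) + fwd, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Upwelling-season bounds from one year of a daily series
#'
#' Accumulates the series from 1 January; the spring transition (STI) is
#' the day of year of the cumulative minimum and the season end (END)
#' and the day of maximum upwelling accumulation (MAX) are both the day
#' of the cumulative maximum. Years in which the maximum precedes the
#' minimum are flagged degenerate.
#'
#' @param x numeric daily series for one calendar year (day 1 = 1 Jan).
#' @return list with `sti`, `end`, `max_day` (days of year) and logical
#'   `degenerate`.
#' @export
season_bounds <- function(x) {
  if (length(x) == 0 || all(is.na(x))) stop("all-missing year")
  cs <- cumsum(ifelse(is.na(x), 0, x))
  sti <- which.min(cs)
  end <- which.max(cs)
  list(sti = sti, end = end, max_day = end, degenerate = end < sti)
}

#' Total upwelling magnitude and season length
#'
#' TUMI is the cumulative upwelling re-accumulated from the spring
#' transition, evaluated at the season end (the sum of the series over
#' days `sti + 1` to `end`); LUSI is the number of days between the
#' spring transition and the season end.
#'
#' @param x numeric daily series for one year.
#' @param sti,end season bounds (days of year) from [season_bounds()].
#' @return list with `tumi` and `lusi`.
#' @export
tumi_lusi <- function(x, sti, end) {
  if (sti > end) stop("degenerate year: spring transition after season end")
  tumi <- if (end == sti) 0 else sum(x[(sti + 1):end])
  list(tumi = tumi, lusi = end - sti)
}

#' Long-term in-season relaxation threshold
#'
#' The relaxation threshold for a latitude bin is the mean of the
#' smoothed daily index over all in-season days (spring transition,
#' exclusive, through season end, inclusive), pooled across all study
#' years.
#'
#' @param series list of numeric daily series, one per year (smoothed).
#' @param sti,end numeric vectors of season bounds per year.
#' @return pooled mean (same units as the series).
#' @export
relaxation_threshold <- function(series, sti, end) {
  stopifnot(length(series) == length(sti), length(series) == length(end))
  vals <- unlist(lapply(seq_along(series), function(i) {
    if (end[i] <= sti[i]) return(numeric(0))
    series[[i]][(sti[i] + 1):end[i]]
  }), use.names = FALSE)
  if (length(vals) == 0) stop("no in-season days")
  mean(vals)
}

#' Annual upwelling phenology per latitude bin
#'
#' Smooths the daily series per latitude bin, computes season bounds,
#' TUMI and LUSI for each year, and the long-term in-season relaxation
#' threshold per bin pooled across all years supplied.
#'
#' @param cuti data frame with columns `date`, `lat_bin`, `cuti` (daily,
#'   contiguous within each year).
#' @param window smoothing window in days (default 10).
#' @return data frame with one row per (lat_bin, year): `sti`, `end`,
#'   `max_day`, `tumi`, `lusi`, `threshold`, `degenerate`.
#' @export
upwelling_phenology <- function(cuti, window = 10) {
  stopifnot(all(c("date", "lat_bin", "cuti") %in% names(cuti)))
  cuti <- cuti[order(cuti$lat_bin, cuti$date), ]
  out <- list()
  for (bin in sort(unique(cuti$lat_bin))) {
    cb <- cuti[cuti$lat_bin == bin, ]
    sm <- smooth_cuti(cb$cuti, window)
    yr <- as.integer(format(cb$date, "%Y"))
    years <- sort(unique(yr))
    rows <- lapply(years, function(y) {
      x <- sm[yr == y]
      b <- season_bounds(x)
      tl <- if (b$degenerate) list(tumi = NA_real_, lusi = NA_real_)
            else tumi_lusi(x, b$sti, b$end)
      data.frame(lat_bin = bin, year = y, sti = b$sti, end = b$end,
                 max_day = b$max_day, tumi = tl$tumi, lusi = tl$lusi,
                 degenerate = b$degenerate)
    })
    rows <- do.call(rbind, rows)
    ok <- !rows$degenerate
    rows$threshold <- relaxation_threshold(
      lapply(years[ok], function(y) sm[yr == y]),
      rows$sti[ok], rows$end[ok])
    out[[as.character(bin)]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative upwelling and relaxation for one (smoothed) yearly series
#'
#' Given an already-smoothed daily series and the year's phenology,
#' computes the cumulative index re-accumulated from the spring
#' transition (zero on and before the STI), flags in-season days whose
#' value falls strictly below the relaxation threshold, and counts the
#' cumulative relaxation days since the spring transition.
#'
#' @param x smoothed daily series (day 1 = 1 Jan).
#' @param sti,end season bounds (days of year).
#' @param threshold relaxation threshold (same units as `x`).
#' @return data frame `doy`, `cumulative_cuti`, `is_relaxation`,
#'   `cumulative_relaxation`.
#' @export
relaxation_state <- function(x, sti, end, threshold) {
  doy <- seq_along(x)
  post <- doy > sti
  cum <- numeric(length(x))
  cum[post] <- cumsum(x[post])
  relax <- post & doy <= end & x < threshold
  data.frame(doy = doy, cumulative_cuti = cum, is_relaxation = relax,
             cumulative_relaxation = cumsum(relax))
}

#' Daily upwelling state: cumulative upwelling and relaxation
#'
#' For every day and latitude bin, computes the smoothed index, the
#' cumulative smoothed index re-accumulated from the spring transition
#' (zero on and before the STI), the relaxation flag (an in-season day
#' whose smoothed index falls strictly below the bin's long-term
#' threshold), and the cumulative count of relaxation days since the
#' spring transition.
#'
#' @param cuti data frame with `date`, `lat_bin`, `cuti`.
#' @param phenology output of [upwelling_phenology()].
#' @param window smoothing window in days (must match the phenology run).
#' @return data frame with `date`, `year`, `doy`, `lat_bin`,
#'   `cuti_smoothed`, `cumulative_cuti`, `is_relaxation`,
#'   `cumulative_relaxation`.
#' @export
daily_upwelling_state <- function(cuti, phenology, window = 10) {
  cuti <- cuti[order(cuti$lat_bin, cuti$date), ]
  out <- list()
  for (bin in sort(unique(cuti$lat_bin))) {
    cb <- cuti[cuti$lat_bin == bin, ]
    sm <- smooth_cuti(cb$cuti, window)
    yr <- as.integer(format(cb$date, "%Y"))
    for (y in sort(unique(yr))) {
      sel <- yr == y
      x <- sm[sel]
      doy <- seq_along(x)
      ph <- phenology[phenology$lat_bin == bin & phenology$year == y, ]
      if (nrow(ph) != 1) stop("phenology missing for bin ", bin, " year ", y)
      rs <- relaxation_state(x, ph$sti, ph$end, ph$threshold)
      out[[paste(bin, y)]] <- data.frame(
        date = cb$date[sel], year = y, doy = doy, lat_bin = bin,
        cuti_smoothed = x, cumulative_cuti = rs$cumulative_cuti,
        is_relaxation = rs$is_relaxation,
        cumulative_relaxation = rs$cumulative_relaxation)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stock-level annual phenology means
#'
#' Averages each phenology index (STI, MAX, TUMI, LUSI) over the
#' 1-degree latitude bins whose interval `[bin, bin + 1)` intersects the
#' stock's latitude range; partially overlapping bins are counted fully.
#'
#' @param phenology output of [upwelling_phenology()].
#' @param stocks named list of `c(lat_min, lat_max)` latitude ranges.
#' @return data frame with one row per (stock, year): `sti`, `max_day`,
#'   `tumi`, `lusi`.
#' @export
stock_phenology_means <- function(phenology, stocks) {
  out <- list()
  for (st in names(stocks)) {
    rng <- stocks[[st]]
    bins <- unique(phenology$lat_bin)
    keep <- bins[bins < rng[2] & (bins + 1) > rng[1]]
    if (length(keep) == 0) stop("no latitude bin overlaps stock ", st)
    ph <- phenology[phenology$lat_bin %in% keep, ]
    agg <- stats::aggregate(ph[c("sti", "max_day", "tumi", "lusi")],
                            by = list(year = ph$year), FUN = mean)
    agg$stock <- st
    out[[st]] <- agg[c("stock", "year", "sti", "max_day", "tumi", "lusi")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
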