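# Model-ready survey segments: counts summed over sightings, conditions
# averaged, covariates extracted at the segment centroid, effective
# strip width evaluated at segment conditions, and the effective-area
# offset 2 * (ESW / 1000) * length used by the density surface model.

#' Assign a stock label by latitude
#'
#' @param lat latitudes (decimal degrees).
#' @param stocks named list of `c(lat_min, lat_max)` ranges that
#'   partition the study area; a centroid on a shared boundary is
#'   assigned to the southern stock.
#' @return character vector of stock labels.
#' @export
assign_stock <- function(lat, stocks) {
  lo <- vapply(stocks, `[[`, numeric(1), 1)
  hi <- vapply(stocks, `[[`, numeric(1), 2)
  ord <- order(lo)  # south to north
  out <- rep(NA_character_, length(lat))
  for (k in rev(ord)) {  # southern ranges claim boundaries last
    inside <- lat >= lo[k] & lat <= hi[k]
    out[inside] <- names(stocks)[k]
  }
  if (anyNA(out)) {
    stop("latitude outside all stock ranges: ",
         paste(signif(lat[is.na(out)][1], 5), collapse = ", "))
  }
  out
}

#' Build the model-ready segment table
#'
#' Joins effort, sightings, static and dynamic covariates, and the
#' fitted detection function into one row per surveyed segment:
#' `n_porpoises` (individuals summed over the segment's sightings; zero
#' counts are retained), mean observation conditions, static covariates
#' at the centroid, dynamic covariates keyed by date and 1-degree
#' latitude bin, ESW at the segment's conditions, and the effective-area
#' offset `offset_area = 2 * (esw/1000) * length` in km^2. Segments with
#' missing covariates (centroid off the grid, shelf width undefined) are
#' dropped with a warning.
#'
#' @param effort a `survey_effort` table.
#' @param sightings a `survey_sightings` table; every sighting must
#'   reference an existing segment.
#' @param static a `static_stack`.
#' @param daily_state a [daily_upwelling_state()] table.
#' @param sst data frame `date`, `lat_bin`, `sst`.
#' @param detection a fitted `detection_model`.
#' @param stocks named list of stock latitude ranges.
#' @return data frame of class `survey_segments`.
#' @export
build_segments <- function(effort, sightings, static, daily_state, sst,
                           detection, stocks) {
  if (nrow(sightings) > 0 &&
      !all(sightings$segment_id %in% effort$segment_id)) {
    stop("sighting references an unknown segment")
  }
  counts <- if (nrow(sightings) > 0) {
    stats::aggregate(list(n_porpoises = sightings$size),
                     by = list(segment_id = sightings$segment_id), FUN = sum)
  } else data.frame(segment_id = character(0), n_porpoises = integer(0))
  seg <- effort[c("segment_id", "psu", "year", "occasion", "date", "type",
                  "cx", "cy", "length_km", "bss", "sightability",
                  "lat", "lat_bin")]
  seg$n_porpoises <- counts$n_porpoises[match(seg$segment_id, counts$segment_id)]
  seg$n_porpoises[is.na(seg$n_porpoises)] <- 0L

  st <- static_extract(static, seg$cx, seg$cy)
  seg$depth <- st$depth
  seg$dist_coast <- st$dist_coast
  seg$shelf_width <- st$shelf_width
  seg$dist_cape <- st$dist_cape
  seg$dist_estuary <- st$dist_estuary
  seg$substrate <- st$substrate

  key <- paste(seg$date, seg$lat_bin)
  dk <- paste(daily_state$date, daily_state$lat_bin)
  seg$cumulative_cuti <- daily_state$cumulative_cuti[match(key, dk)]
  seg$cumulative_relaxation <- daily_state$cumulative_relaxation[match(key, dk)]
  sk <- paste(sst$date, sst$lat_bin)
  seg$sst <- sst$sst[match(key, sk)]

  seg$esw_m <- esw(detection, seg)
  seg$offset_area <- 2 * (seg$esw_m / 1000) * seg$length_km
  seg$stock <- assign_stock(seg$lat, stocks)

  has_cape <- nrow(attr(static, "capes")) > 0
  need <- c("depth", "dist_coast", "shelf_width", "dist_estuary",
            "substrate", "cumulative_cuti", "cumulative_relaxation", "sst",
            if (has_cape) "dist_cape")
  complete <- stats::complete.cases(seg[need])
  if (any(!complete)) {
    warning(sum(!complete), " segment(s) dropped for missing covariates")
    seg <- seg[complete, ]
  }
  rownames(seg) <- NULL
  class(seg) <- c("survey_segments", "data.frame")
  seg
}

#' Encounter-rate summaries
#'
#' Porpoises per km of effort, stratified by year, by latitude bin, or
#' by year and latitude bin. Strata without effort are reported as
#' missing (NA rate), distinct from surveyed strata with no sightings
#' (rate 0). Strata with less effort than `min_effort_km` are flagged
#' unstable.
#'
#' @param segments a `survey_segments` table.
#' @param by `"year"`, `"lat_bin"`, or `"year_lat_bin"`.
#' @param bin_width latitude bin width in degrees (default 0.1; the
#'   coarser 1-degree summary used in mapping figures is available by
#'   setting 1).
#' @param min_effort_km effort below which a stratum is flagged.
#' @return data frame with the stratum columns, `effort_km`,
#'   `porpoises`, `rate` (porpoises per km), and `low_effort`.
#' @export
encounter_rates <- function(segments, by = c("year", "lat_bin", "year_lat_bin"),
                            bin_width = 0.1, min_effort_km = 1) {
  by <- match.arg(by)
  if (nrow(segments) == 0) stop("no segments")
  if (sum(segments$length_km) <= 0) stop("zero total effort")
  bin <- floor(segments$lat / bin_width) * bin_width
  strata <- switch(by,
    year = data.frame(year = segments$year),
    lat_bin = data.frame(lat_bin = bin),
    year_lat_bin = data.frame(year = segments$year, lat_bin = bin))
  agg <- stats::aggregate(
    cbind(effort_km = segments$length_km, porpoises = segments$n_porpoises),
    by = strata, FUN = sum)
  if (by == "year_lat_bin") {
    full <- expand.grid(year = sort(unique(segments$year)),
                        lat_bin = sort(unique(bin)))
    agg <- merge(full, agg, by = c("year", "lat_bin"), all.x = TRUE)
  }
  agg$rate <- agg$porpoises / agg$effort_km
  agg$low_effort <- !is.na(agg$effort_km) & agg$effort_km < min_effort_km
  agg[order(agg[[1]]), , drop = FALSE]
}
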