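# Annual density anomalies versus large-scale environmental correlates:
# spring (February-May) means of basin-scale climate indices (PDO, MEI)
# and stock-level upwelling phenology (STI, MAX, TUMI, LUSI), related by
# linear models with stock interactions and sequential ANOVA.

#' Spring (February-May) mean of a monthly climate index
#'
#' @param monthly data frame with columns `year`, `month`, `value`.
#' @return data frame `year`, `value` with the arithmetic mean of the
#'   February, March, April and May values; years missing any of the
#'   four months get NA with a warning.
#' @export
spring_mean <- function(monthly) {
  years <- sort(unique(monthly$year))
  out <- data.frame(year = years, value = NA_real_)
  for (i in seq_along(years)) {
    v <- monthly$value[monthly$year == years[i] & monthly$month %in% 2:5]
    months <- monthly$month[monthly$year == years[i] & monthly$month %in% 2:5]
    if (length(unique(months)) == 4 && !anyNA(v)) {
      out$value[i] <- mean(v)
    } else {
      warning("year ", years[i], " missing spring months; set to NA")
    }
  }
  out
}

#' Simulate a monthly basin-scale climate index
#'
#' AR(1) monthly series, a simple stand-in for PDO/MEI-like indices in
#' synthetic experiments.
#'
#' @param years integer years.
#' @param seed integer seed.
#' @param ar AR(1) coefficient (default 0.8).
#' @param sd innovation SD (default 0.5).
#' @return data frame `year`, `month`, `value`.
#' @export
simulate_climate_index <- function(years, seed = 1, ar = 0.8, sd = 0.5) {
  set.seed(seed)
  n <- 12 * length(years)
  v <- as.numeric(stats::filter(stats::rnorm(n, 0, sd), ar, method = "recursive"))
  data.frame(year = rep(years, each = 12), month = rep(1:12, length(years)),
             value = v)
}

#' Stock-level phenology regressor table
#'
#' Reshapes [stock_phenology_means()] output into the per-(stock, year)
#' regressor table joined to the annual density series: STI, MAX, TUMI
#' and LUSI columns keyed by stock and year.
#'
#' @param stock_means output of [stock_phenology_means()].
#' @return data frame `stock`, `year`, `sti`, `max_day`, `tumi`, `lusi`.
#' @export
phenology_regressors <- function(stock_means) {
  stock_means[c("stock", "year", "sti", "max_day", "tumi", "lusi")]
}

#' Linear trend model of density anomaly on an environmental index
#'
#' Ordinary least squares of the standardized annual density anomaly on
#' an environmental index with stock as a factor and a stock x index
#' interaction (dropped with a warning when only one stock is present).
#' Main and interaction effects are assessed by sequential (type I)
#' ANOVA with the index entered first; per-stock slopes combine the
#' index coefficient with the stock's interaction contrast.
#'
#' @param data data frame with columns `anomaly`, `index`, `stock`
#'   (rows with missing values are dropped).
#' @param index_name label for reporting.
#' @return object of class `trend_fit`: list with `lm`, `anova`
#'   (sequential table), `overall_p` (model F test), `slopes` (per-stock
#'   data frame), `index_name`.
#' @export
fit_trend <- function(data, index_name = "index") {
  dat <- data[stats::complete.cases(data[c("anomaly", "index", "stock")]), ]
  dat$stock <- factor(dat$stock)
  if (nlevels(dat$stock) < 2) {
    warning("single stock: interaction dropped")
    m <- stats::lm(anomaly ~ index, data = dat)
  } else {
    if (min(table(dat$stock)) < 3) stop("need >= 3 years per stock")
    m <- stats::lm(anomaly ~ index * stock, data = dat)
  }
  an <- stats::anova(m)
  fs <- summary(m)$fstatistic
  overall_p <- if (is.null(fs)) NA_real_ else
    as.numeric(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  cf <- stats::coef(m)
  lv <- levels(dat$stock)
  slopes <- data.frame(stock = lv, slope = cf[["index"]])
  for (s in lv[-1]) {
    nm <- paste0("index:stock", s)
    if (nm %in% names(cf)) {
      slopes$slope[slopes$stock == s] <- cf[["index"]] + cf[[nm]]
    }
  }
  structure(list(lm = m, anova = an, overall_p = overall_p,
                 slopes = slopes, index_name = index_name),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> anomaly ~ %s x stock\n", x$index_name))
  cat(sprintf("  overall model p = %.4g\n", x$overall_p))
  an <- x$anova
  for (r in rownames(an)) {
    if (r == "Residuals") next
    cat(sprintf("  %-14s p = %.4g %s\n", r, an[r, "Pr(>F)"],
                significance_label(an[r, "Pr(>F)"])))
  }
  cat("  per-stock slopes:\n")
  for (i in seq_len(nrow(x$slopes))) {
    cat(sprintf("    %s: %.3f\n", x$slopes$stock[i], x$slopes$slope[i]))
  }
  invisible(x)
}

# reporting tiers: *** / ** / * / marginal (.) / ns
significance_label <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "." else "ns"
}
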