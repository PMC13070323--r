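test_that("ExDet reproduces hand-computed range extrapolation", {
  ref <- data.frame(a = seq(0, 10, length.out = 11), b = rnorm(11))
  pt <- data.frame(a = -1, b = mean(ref$b))
  # UD for covariate a: (-1 - 0) / 10 = -0.1; b contributes 0
  expect_equal(exdet(ref, pt), -0.1)
  # reference points themselves are analog: values in [0, 1]
  vals <- exdet(ref, ref)
  expect_true(all(vals >= 0 & vals <= 1))
  # the most extreme reference point scores exactly 1
  d2 <- stats::mahalanobis(as.matrix(ref), colMeans(ref), cov(ref))
  expect_equal(exdet(ref, ref[which.max(d2), ]), 1)
  expect_error(exdet(data.frame(a = c(1, 1), b = 1:2), pt), "zero reference")
})

test_that("ExDet matches the brute-force oracle on random points", {
  set.seed(7)
  ref <- data.frame(x = rnorm(200), y = rnorm(200), z = runif(200))
  ref$y <- ref$y + 0.7 * ref$x
  pts <- data.frame(x = rnorm(1000, 0, 2), y = rnorm(1000, 0, 2),
                    z = runif(1000, -0.5, 1.5))
  expect_equal(exdet(ref, pts), exdet_oracle(ref, pts), tolerance = 1e-10)
})

test_that("day filtering drops exactly the days violating the thresholds", {
  set.seed(8)
  # correlated 2-covariate reference so NT2 > 1 can occur inside ranges
  ref <- data.frame(u = rnorm(300), v = 0)
  ref$v <- 0.95 * ref$u + rnorm(300, 0, 0.2)
  mu <- colMeans(ref); S <- cov(ref)
  d2max <- max(stats::mahalanobis(as.matrix(ref), mu, S))
  # construct points with prescribed NT2 along the minor axis
  minor <- eigen(S)$vectors[, 2]
  pt_at <- function(nt2) {
    t <- sqrt(nt2 * d2max / as.numeric(minor %*% solve(S, minor)))
    p <- mu + t * minor
    stopifnot(p[1] > min(ref$u), p[1] < max(ref$u),
              p[2] > min(ref$v), p[2] < max(ref$v))  # inside univariate ranges
    p
  }
  inside <- unname(c(mu[1], mu[2]))
  p110 <- pt_at(1.10); p120 <- pt_at(1.20)
  day_covs <- data.frame(
    date = as.Date("2001-06-01") + rep(0:3, each = 2),
    u = c(inside[1], inside[1],        # day 1: all analog -> kept
          inside[1], min(ref$u) - 0.4, # day 2: NT1 = -0.2 -> dropped
          inside[1], p110[1],          # day 3: NT2 = 1.10 <= 1.15 -> kept
          inside[1], p120[1]),         # day 4: NT2 = 1.20 -> dropped
    v = c(inside[2], inside[2], inside[2], mu[2], inside[2], p110[2],
          inside[2], p120[2]))
  # make day 2's NT1 exactly -0.2 on covariate u
  span_u <- diff(range(ref$u))
  day_covs$u[4] <- min(ref$u) - 0.2 * span_u
  fd <- filter_days(day_covs, ref)
  expect_equal(fd$days$keep, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(fd$values$exdet[4], -0.2, tolerance = 1e-9)
})

test_that("an intercept-only model predicts constant density", {
  set.seed(9)
  n <- 800
  area <- runif(n, 0.5, 1.5)
  seg <- data.frame(offset_area = area, n_porpoises = rpois(n, 1.7 * area),
                    stock = "one")
  class(seg) <- c("survey_segments", "data.frame")
  f <- fit_dsm(seg, smooth_terms = character(), include_interaction = FALSE)
  grid <- data.frame(cell_id = 1:10, area_km2 = rep(c(20, 25), 5))
  pred <- predict_density(f, grid)
  expect_equal(pred$density, rep(exp(coef(f$gam)[1]), 10), ignore_attr = TRUE)
  expect_equal(pred$abundance, pred$density * pred$area_km2)
  # training rows reproduce fitted values
  tr <- seg
  tr$area_km2 <- tr$offset_area
  expect_equal(predict_density(f, tr)$abundance,
               unname(fitted(f$gam)), tolerance = 1e-8)
})

test_that("anomalies are z-scores and degenerate inputs raise errors", {
  expect_equal(density_anomaly(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(10)
  for (r in 1:20) {
    x <- rnorm(sample(3:31, 1), sd = runif(1, 0.1, 5))
    a <- density_anomaly(x)
    expect_equal(mean(a), 0, tolerance = 1e-12)
    expect_equal(sd(a), 1, tolerance = 1e-12)
  }
  expect_error(density_anomaly(rep(2, 5)), "zero variance")
  expect_error(density_anomaly(1), "at least 2")
})

test_that("coefficient-simulation CV matches the lognormal closed form", {
  set.seed(11)
  n <- 600
  area <- runif(n, 0.5, 1.5)
  seg <- data.frame(offset_area = area, n_porpoises = rpois(n, 2 * area),
                    stock = "one")
  class(seg) <- c("survey_segments", "data.frame")
  f <- fit_dsm(seg, smooth_terms = character(), include_interaction = FALSE)
  grid <- data.frame(cell_id = 1:4, area_km2 = c(10, 20, 30, 40))
  cv <- prediction_cv(f, grid, n_draws = 1000, seed = 1)
  v <- as.numeric(vcov(f$gam))
  closed <- sqrt(exp(v) - 1)  # CV of a lognormal with log-variance v
  expect_equal(unname(cv$group_cv$cv), closed, tolerance = 0.05)
  # CV is invariant to a global rescaling of cell areas
  grid2 <- grid
  grid2$area_km2 <- grid$area_km2 * 10
  cv2 <- prediction_cv(f, grid2, n_draws = 1000, seed = 1)
  expect_equal(cv$group_cv$cv, cv2$group_cv$cv, tolerance = 1e-12)
  # doubling the draws moves the estimate by less than 3 Monte-Carlo SEs
  cv4 <- prediction_cv(f, grid, n_draws = 2000, seed = 2)
  mc_se <- closed / sqrt(2 * 1000)
  expect_lt(abs(cv4$group_cv$cv[1] - closed), 3 * mc_se + 3 * closed / sqrt(2 * 2000))
  # zero coefficient covariance: degenerate draws, CV exactly 0
  draws <- porpoisedsm:::rmvn_eig(50, c(1, 2), matrix(0, 2, 2))
  expect_true(all(draws[, 1] == 1 & draws[, 2] == 2))
})

test_that("the prediction pipeline sums abundance consistently", {
  fx_w <- generate_world(tiny_config(), seed = 30, years = 2001:2002)
  eff <- simulate_surveys(fx_w, years = 2001:2002, occasions_per_year = 2,
                          seed = 30)
  phen <- upwelling_phenology(fx_w$cuti)
  daily <- daily_upwelling_state(fx_w$cuti, phen)
  s <- simulate_sightings(fx_w, eff, seed = 30, daily_state = daily)
  tr <- truncate_distances(s$distance_m)
  det <- fit_detection(s[tr$keep, ], "hn", w = tr$w)
  static <- rasterize_static(fx_w, smooth_window = 60)
  stocks <- list(all = c(40, 41))
  seg <- suppressWarnings(build_segments(eff, s, static, daily, fx_w$sst,
                                         det, stocks))
  f <- fit_dsm(seg, stock = "all",
               drop_terms = if (nrow(attr(static, "capes")) == 0) "dist_cape")
  grid <- prediction_grid(fx_w, static, stocks)
  ps <- predict_surface(f, grid, daily, fx_w$sst, years = 2001:2002)
  pred <- ps$predictions
  expect_true(all(is.finite(pred$abundance)))
  expect_equal(pred$abundance, pred$density * pred$area_km2)
  # per-day totals equal the area-weighted density integral
  one <- pred[pred$date == pred$date[1], ]
  expect_equal(sum(one$abundance), sum(one$density * one$area_km2))
  summ <- summarize_predictions(pred)
  expect_equal(nrow(summ$annual), 2)
  expect_true(all(abs(tapply(summ$annual$anomaly, summ$annual$stock, mean)) < 1e-12))
})
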