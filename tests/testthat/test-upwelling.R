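test_that("running-mean smoother matches the brute-force windowed mean", {
  expect_equal(smooth_cuti(rep(3.2, 50)), rep(3.2, 50))
  x <- rep(0, 30); x[15] <- 10
  expect_equal(max(smooth_cuti(x, 10)), 1.0)
  expect_error(smooth_cuti(numeric(0)), "empty")
  set.seed(1)
  y <- rnorm(365)
  sm <- smooth_cuti(y, 10)
  for (i in sample(365, 100)) {
    expect_equal(sm[i], mean(y[max(1, i - 4):min(365, i + 5)]))
  }
})

test_that("season bounds come from the cumulative-sum extrema", {
  x <- c(rep(-1, 50), rep(1, 200), rep(-1, 115))
  b <- season_bounds(x)
  expect_equal(b$sti, 50)
  expect_equal(b$end, 250)
  expect_equal(b$max_day, 250)
  expect_false(b$degenerate)
  tl <- tumi_lusi(x, b$sti, b$end)
  expect_equal(tl$tumi, 200)
  expect_equal(tl$lusi, 200)
  # all-positive series: minimum of the cumulative sum at day 1
  expect_equal(season_bounds(rep(0.5, 365))$sti, 1)
  # translation equivariance
  x10 <- c(rep(-1, 60), rep(1, 200), rep(-1, 105))
  b10 <- season_bounds(x10)
  expect_equal(b10$sti, 60)
  expect_equal(b10$end, 260)
  # degenerate year: upwelling only declines
  expect_true(season_bounds(c(rep(1, 50), rep(-1, 315)))$degenerate)
  expect_error(tumi_lusi(x, 250, 50), "degenerate")
  expect_error(season_bounds(rep(NA_real_, 10)), "missing")
})

test_that("TUMI is the in-season re-zeroed cumulative sum and is non-negative", {
  x <- c(rep(-1, 50), rep(0, 200), rep(-1, 115))
  expect_equal(tumi_lusi(x, 50, 250)$tumi, 0)
  set.seed(2)
  for (r in 1:200) {
    y <- rnorm(365, mean = 0.1, sd = 1)
    b <- season_bounds(y)
    if (b$degenerate) next
    tl <- tumi_lusi(y, b$sti, b$end)
    expect_gte(tl$tumi, 0)
    expect_equal(tl$lusi, b$end - b$sti)
  }
})

test_that("the relaxation threshold pools in-season days across years", {
  expect_equal(relaxation_threshold(list(rep(2, 365)), 50, 250), 2)
  y1 <- rep(1, 365); y2 <- rep(3, 365)
  expect_equal(relaxation_threshold(list(y1, y2), c(50, 50), c(250, 250)), 2)
  # invariant to out-of-season values
  y1b <- y1; y1b[1:50] <- 99; y1b[251:365] <- -99
  expect_equal(relaxation_threshold(list(y1b, y2), c(50, 50), c(250, 250)), 2)
  expect_error(relaxation_threshold(list(y1), 250, 250), "in-season")
})

test_that("relaxation days are counted cumulatively since the spring transition", {
  # post-STI series alternating 0, 1 with threshold 0.5: five of the
  # first ten in-season days are relaxation days
  x <- c(rep(1, 100), rep(c(0, 1), 100), rep(1, 65))
  rs <- relaxation_state(x, sti = 100, end = 300, threshold = 0.5)
  expect_equal(rs$cumulative_relaxation[110], 5)
  expect_true(all(rs$cumulative_relaxation[1:100] == 0))
  expect_true(all(diff(rs$cumulative_relaxation) >= 0))
  # exactly the in-season sub-threshold days are flagged
  expect_equal(which(rs$is_relaxation),
               which(seq_along(x) > 100 & seq_along(x) <= 300 & x < 0.5))
  # all days above threshold: no relaxation at all
  rs2 <- relaxation_state(rep(1, 365), 100, 300, 0.5)
  expect_true(all(rs2$cumulative_relaxation == 0))
  # monotone on random series
  set.seed(3)
  for (r in 1:50) {
    y <- rnorm(365)
    rs3 <- relaxation_state(y, 80, 280, 0)
    expect_true(all(diff(rs3$cumulative_relaxation) >= 0))
  }
})

test_that("phenology pipeline is consistent across modules", {
  w <- generate_world(tiny_config(), seed = 5, years = 2001:2003)
  ph <- upwelling_phenology(w$cuti)
  expect_true(all(ph$sti <= ph$end))
  expect_equal(ph$lusi, ph$end - ph$sti)
  expect_true(all(ph$tumi >= 0))
  ds <- daily_upwelling_state(w$cuti, ph)
  expect_true(all(ds$cumulative_cuti[ds$doy <= 30] == 0))
  for (g in split(ds, list(ds$lat_bin, ds$year))) {
    expect_true(all(diff(g$cumulative_relaxation) >= 0))
  }
})

test_that("stock phenology means average the overlapping latitude bins", {
  ph <- data.frame(lat_bin = c(40, 41), year = c(2001, 2001),
                   sti = c(100, 120), end = c(250, 270),
                   max_day = c(250, 270), tumi = c(150, 170),
                   lusi = c(150, 150), threshold = c(0.5, 0.5))
  one <- stock_phenology_means(ph, list(a = c(40.2, 40.9)))
  expect_equal(one$sti, 100)
  both <- stock_phenology_means(ph, list(a = c(40, 42)))
  expect_equal(both$sti, 110)
  expect_equal(both$max_day, 260)
  expect_error(stock_phenology_means(ph, list(a = c(50, 51))), "overlaps")
  # brute-force over random ranges
  set.seed(4)
  for (r in 1:20) {
    lo <- runif(1, 39, 42); hi <- lo + runif(1, 0.3, 2)
    bins <- ph$lat_bin[ph$lat_bin < hi & ph$lat_bin + 1 > lo]
    if (length(bins) == 0) next
    got <- stock_phenology_means(ph, list(s = c(lo, hi)))
    expect_equal(got$tumi, mean(ph$tumi[ph$lat_bin %in% bins]))
  }
})
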