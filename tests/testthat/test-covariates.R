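test_that("smoothing a straight coastline leaves it on the same line", {
  coast <- data.frame(x = rep(0, 201), y = seq(0, 100, by = 0.5))
  sm <- smooth_coastline(coast, window = 40)
  expect_equal(sm$x, rep(0, 201))
  expect_error(smooth_coastline(coast, window = 200), "arc length")
})

test_that("a 200 km window flattens a triangular promontory to < 1 km", {
  coast <- triangle_coast(length_km = 300, apex_km = 8, base_km = 20)
  sm <- smooth_coastline(coast, window = 200)
  apex_idx <- which.max(coast$x)
  expect_lt(sm$x[apex_idx], 1)
  # hand computation: windowed mean of x over a full 200 km window is the
  # triangle area (0.5 * 8 * 20 = 80 km^2) / 200 km = 0.4 km
  expect_equal(sm$x[apex_idx], 80 / 200, tolerance = 0.05)
  # smoothing twice moves vertices less than smoothing once
  sm2 <- smooth_coastline(sm, window = 200)
  d1 <- max(sqrt((sm$x - coast$x)^2 + (sm$y - coast$y)^2))
  d2 <- max(sqrt((sm2$x - sm$x)^2 + (sm2$y - sm$y)^2))
  expect_lt(d2, d1)
})

test_that("cape detection applies the 5 km threshold to coastline excursions", {
  straight <- data.frame(x = rep(0, 601), y = seq(0, 300, by = 0.5))
  sm0 <- smooth_coastline(straight, window = 200)
  expect_equal(nrow(detect_capes(straight, sm0)), 0)

  coast8 <- triangle_coast(apex_km = 8)
  capes8 <- detect_capes(coast8, smooth_coastline(coast8, window = 200))
  expect_equal(nrow(capes8), 1)
  expect_equal(capes8$y, 150, tolerance = 1)   # cape sits at the apex
  expect_gt(capes8$offset_km, 5)

  coast4 <- triangle_coast(apex_km = 4)
  capes4 <- detect_capes(coast4, smooth_coastline(coast4, window = 200))
  expect_equal(nrow(capes4), 0)
})

test_that("cape distances are negative north of the nearest cape", {
  cape <- structure(data.frame(x = 0, y = 0, s = 0, offset_km = 8),
                    class = c("cape_set", "data.frame"))
  expect_equal(distance_to_cape(0, 10, cape), -10)
  expect_equal(distance_to_cape(0, -10, cape), 10)
  expect_equal(distance_to_cape(0, 0, cape), 0)
  two <- structure(data.frame(x = c(0, 0), y = c(0, 100), s = c(0, 100),
                              offset_km = c(8, 8)),
                   class = c("cape_set", "data.frame"))
  expect_equal(distance_to_cape(0, 30, two), -30)
  expect_error(distance_to_cape(0, 0, two[0, ]), "empty cape set")
  # brute-force oracle on random points
  set.seed(1)
  px <- runif(50, -20, 20); py <- runif(50, -50, 150)
  oracle <- vapply(seq_along(px), function(i) {
    d <- sqrt((px[i] - two$x)^2 + (py[i] - two$y)^2)
    k <- which.min(d)
    if (py[i] > two$y[k]) -d[k] else d[k]
  }, numeric(1))
  expect_equal(distance_to_cape(px, py, two), oracle)
})

test_that("shelf width finds the 200 m isobath by linear interpolation", {
  grid <- porpoisedsm:::make_grid_frame(0, 20, 0, 3, 1)
  coast <- data.frame(x = c(0, 0), y = c(0, 3))
  grid$depth <- 20 * grid$x
  expect_equal(shelf_width(grid, coast)$shelf_width, rep(10, 3))
  # plateau at 150 m stepping to 250 m at 15 km: crossing interpolates to 15
  grid$depth <- ifelse(grid$x < 15, 150, 250)
  expect_equal(shelf_width(grid, coast)$shelf_width, rep(15, 3))
  # widening the shelf (gentler slope) increases the width
  g1 <- grid; g1$depth <- 20 * grid$x
  g2 <- grid; g2$depth <- 12 * grid$x
  expect_true(all(shelf_width(g2, coast)$shelf_width >
                    shelf_width(g1, coast)$shelf_width))
  # isobath outside the grid: flagged missing
  g3 <- grid; g3$depth <- 2 * grid$x
  expect_true(all(is.na(shelf_width(g3, coast)$shelf_width)))
})

test_that("estuary distances use only estuaries above the area threshold", {
  est <- data.frame(x = c(5, 20), y = c(0, 0), area_ha = c(250, 400))
  expect_equal(distance_to_estuary(0, 0, est), 20)
  expect_equal(distance_to_estuary(20, 0, est), 0)
  expect_error(distance_to_estuary(0, 0, est[est$area_ha < 300, ]), "hectares")
  set.seed(2)
  est2 <- data.frame(x = runif(10, 0, 50), y = runif(10, 0, 50),
                     area_ha = runif(10, 100, 1000))
  px <- runif(100, 0, 50); py <- runif(100, 0, 50)
  keep <- est2[est2$area_ha > 300, ]
  oracle <- vapply(seq_along(px), function(i) {
    min(sqrt((px[i] - keep$x)^2 + (py[i] - keep$y)^2))
  }, numeric(1))
  expect_equal(distance_to_estuary(px, py, est2), oracle)
})

test_that("the static stack matches pointwise oracles at cell centres", {
  w <- generate_world(tiny_config(), seed = 11, years = 2001)
  stack <- rasterize_static(w, smooth_window = 60)
  sea <- !is.na(stack$depth)
  # distance to a straight stretch of coast equals the offshore coordinate
  ws <- generate_world(straight_config(), seed = 3, years = 2001)
  st_s <- rasterize_static(ws, smooth_window = 60)
  sea_s <- !is.na(st_s$depth)
  expect_equal(st_s$dist_coast[sea_s], st_s$x[sea_s], tolerance = 1e-9)
  # substrate categories preserved exactly
  expect_true(all(stack$substrate[sea] %in% c("hard", "soft")))
  # spot-check 50 cells against the per-point operations
  set.seed(3)
  idx <- sample(which(sea), 50)
  expect_equal(stack$dist_coast[idx],
               porpoisedsm:::dist_to_polyline(stack$x[idx], stack$y[idx],
                                              w$coastline$x, w$coastline$y))
  expect_equal(stack$dist_estuary[idx],
               distance_to_estuary(stack$x[idx], stack$y[idx], w$estuaries))
  capes <- attr(stack, "capes")
  if (nrow(capes) > 0) {
    expect_equal(stack$dist_cape[idx],
                 distance_to_cape(stack$x[idx], stack$y[idx], capes))
  }
  # shelf width is constant along each latitude row
  rows <- split(stack$shelf_width[sea], stack$y[sea])
  expect_true(all(vapply(rows, function(v) length(unique(v)) == 1, logical(1))))
})
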