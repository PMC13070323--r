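simulate_hn <- function(n, sigma, w, seed) {
  set.seed(seed)
  x <- abs(rnorm(ceiling(n * 3), 0, sigma))
  x <- x[x <= w][1:n]
  data.frame(distance_m = x)
}

test_that("truncation uses the linear-interpolation percentile and is idempotent", {
  expect_equal(truncate_distances(rep(100, 30))$w, 100)
  expect_equal(truncate_distances(rep(100, 30))$n_removed, 0)
  tr <- truncate_distances(1:100)
  expect_equal(tr$w, 98.02)          # type-7 98th percentile of 1..100
  expect_equal(tr$n_removed, 2)
  kept <- (1:100)[tr$keep]
  expect_true(all(kept <= tr$w))
  expect_equal(sum(kept <= tr$w), length(kept))  # re-truncation changes nothing
  expect_error(truncate_distances(1:10), "at least 20")
})

test_that("the key functions intercept at one and the scale model is log-linear", {
  expect_equal(porpoisedsm:::detection_g(0, 80, "hn"), 1)
  expect_equal(porpoisedsm:::detection_g(0, 80, "hr", b = 2.5), 1)
  d <- simulate_hn(800, 100, 270.5, seed = 1)
  d$bss <- sample(0:5, nrow(d), TRUE)
  m <- fit_detection(d, "hn", "bss", w = 270.5)
  expect_equal(unname(porpoisedsm:::detection_sigma(m, data.frame(bss = 2))),
               exp(m$beta[["(Intercept)"]] + 2 * m$beta[["bss"]]))
})

test_that("half-normal fits recover the generating scale", {
  sig <- vapply(1:5, function(r) {
    fit_detection(simulate_hn(1500, 100, 270.5, seed = r), "hn",
                  w = 270.5)$sigma0_m
  }, numeric(1))
  expect_true(all(abs(sig - 100) / 100 < 0.1))
})

test_that("the hazard-rate optimum beats a parameter-grid search", {
  set.seed(10)
  w <- 270.5
  # sample 50 hazard-rate distances by rejection from the truncated density
  sigma_true <- 100; b_true <- 2.5
  x <- numeric(0)
  while (length(x) < 50) {
    cand <- runif(200, 0, w)
    keep <- runif(200) < porpoisedsm:::detection_g(cand, sigma_true, "hr", b_true)
    x <- c(x, cand[keep])
  }
  d <- data.frame(distance_m = x[1:50])
  m <- fit_detection(d, "hr", w = w)
  # independent brute-force likelihood: trapezoid mu on a fine grid
  grid_ll <- function(sigma, b) {
    u <- seq(0, w, length.out = 2001)
    g <- 1 - exp(-(u / sigma)^(-b)); g[1] <- 1
    mu <- sum((g[-1] + g[-2001]) / 2) * (w / 2000)
    sum(log(porpoisedsm:::detection_g(d$distance_m, sigma, "hr", b))) -
      50 * log(mu)
  }
  best_grid <- max(outer(seq(50, 200, length.out = 50),
                         seq(1, 5, length.out = 50), Vectorize(grid_ll)))
  expect_gte(m$logL, best_grid - 1e-6)
})

test_that("ESW matches independent quadrature and its limits", {
  w <- 270.5
  hn <- structure(list(key = "hn", covariates = character(),
                       beta = c("(Intercept)" = log(100)), b = NULL,
                       sigma0_m = 100, w = w), class = "detection_model")
  # high-resolution trapezoid oracle
  u <- seq(0, w, length.out = 1e6 + 1)
  oracle <- sum((exp(-u[-1]^2 / 2e4) + exp(-u[-length(u)]^2 / 2e4)) / 2) *
    (w / 1e6)
  expect_equal(esw(hn), oracle, tolerance = 1e-6)
  # closed form via the normal CDF
  closed <- 100 * sqrt(2 * pi) * (pnorm(w / 100) - 0.5)
  expect_lt(abs(esw(hn) - closed), 1e-6 * w)
  # sigma -> infinity: g is 1 on [0, w] so ESW -> w
  wide <- hn; wide$beta <- c("(Intercept)" = log(1e9)); wide$sigma0_m <- 1e9
  expect_equal(esw(wide), w, tolerance = 1e-6)
  # strictly increasing in sigma
  esws <- vapply(c(50, 80, 120, 200), function(s) {
    m <- hn; m$beta <- c("(Intercept)" = log(s)); m$sigma0_m <- s
    esw(m)
  }, numeric(1))
  expect_true(all(diff(esws) > 0))
  expect_true(all(esws > 0 & esws <= w))
})

test_that("AIC selection returns the minimum and breaks ties toward parsimony", {
  d <- simulate_hn(500, 100, 270.5, seed = 2)
  m <- fit_detection(d, "hn", w = 270.5)
  expect_identical(select_detection(list(m)), m)
  m2 <- m; m2$npar <- 3
  expect_equal(select_detection(list(big = m2, small = m))$npar, m$npar)
  cands <- suppressWarnings(fit_detection_candidates(
    d, 270.5, keys = "hn", covariate_sets = list(character())))
  expect_equal(select_detection(cands)$AIC, min(vapply(cands, `[[`,
                                                       numeric(1), "AIC")))
  expect_error(select_detection(list(NULL, NULL)), "no converged")
})

test_that("the conditional likelihood ignores effort without sightings", {
  d <- simulate_hn(400, 100, 270.5, seed = 3)
  m1 <- fit_detection(d, "hn", w = 270.5)
  m2 <- fit_detection(d, "hn", w = 270.5)  # same data, same fit
  expect_equal(m1$sigma0_m, m2$sigma0_m)
  expect_error(fit_detection(data.frame(distance_m = c(-1, 50)), "hn",
                             w = 270.5), "negative")
  expect_error(fit_detection(data.frame(distance_m = c(300, 50)), "hn",
                             w = 270.5), "truncated")
})
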