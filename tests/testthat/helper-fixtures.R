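# Shared fixtures: small worlds and directly constructed segment tables.

tiny_config <- function(...) {
  world_config(coast_length_km = 100, n_promontories = 1,
               promontory_amplitude_km = 8, ...)
}

straight_config <- function(...) {
  world_config(coast_length_km = 100, n_promontories = 0, ...)
}

# a coastline with a single triangular promontory: apex offset (km)
# seaward at the midpoint of a 'base' km wide excursion
triangle_coast <- function(length_km = 300, apex_km = 8, base_km = 20,
                           spacing = 0.5) {
  y <- seq(0, length_km, by = spacing)
  mid <- length_km / 2
  x <- pmax(0, apex_km * (1 - abs(y - mid) / (base_km / 2)))
  data.frame(x = x, y = y)
}

# segment-like table generated straight from a known log-density; counts
# are Poisson with mean exp(eta) * offset_area, so the DSM's quasi-Poisson
# fit should recover the planted smooth effects
make_dsm_segments <- function(n, seed = 1, b0 = log(1),
                              depth_effect = function(d) -((d - 40) / 30)^2,
                              noise_effect = 0) {
  set.seed(seed)
  depth <- runif(n, 0, 100)
  sst <- runif(n, 8, 18)          # pure-noise covariate unless noise_effect != 0
  offset_area <- runif(n, 0.5, 1.5)
  eta <- b0 + depth_effect(depth) + noise_effect * (sst - 13)
  df <- data.frame(
    depth = depth, sst = sst, offset_area = offset_area,
    n_porpoises = rpois(n, exp(eta) * offset_area),
    stock = "one")
  class(df) <- c("survey_segments", "data.frame")
  df
}

# brute-force ExDet oracle: direct NT1/NT2 formulas, one point at a time
exdet_oracle <- function(reference, points) {
  ref <- as.matrix(reference); pts <- as.matrix(points)
  lo <- apply(ref, 2, min); hi <- apply(ref, 2, max)
  mu <- colMeans(ref); S <- stats::cov(ref)
  d2max <- max(stats::mahalanobis(ref, mu, S))
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, ]
    ud <- pmin(x - lo, hi - x, 0) / (hi - lo)
    nt1 <- sum(ud)
    if (nt1 < 0) nt1 else stats::mahalanobis(rbind(x), mu, S) / d2max
  }, numeric(1))
}
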