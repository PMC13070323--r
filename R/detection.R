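# Line-transect detection functions with observation-condition
# covariates (Beaufort sea state, sightability), fitted by maximising
# the conditional likelihood of the perpendicular distances, compared by
# AIC, and summarised as effective strip widths (ESW).
#
# Keys: half-normal g(x) = exp(-x^2 / (2 sigma^2)) and hazard-rate
# g(x) = 1 - exp(-(x / sigma)^-b), b > 0. Covariates act on the scale
# through a log link, sigma_i = exp(beta0 + beta' z_i), the standard
# multiple-covariate distance sampling (MCDS) formulation; the
# hazard-rate shape b is shared across covariate levels. g(0) = 1 by
# construction for both keys, and no availability or perception bias
# correction is applied (assumed absent or constant).

#' Truncate perpendicular distances at a percentile
#'
#' Sets the truncation distance w to the given percentile of the
#' observed perpendicular distances (type-7 quantile: linear
#' interpolation between order statistics) and discards observations
#' beyond it.
#'
#' @param distances perpendicular distances in m.
#' @param percentile truncation percentile (default 98).
#' @return list with `w` (m), `keep` (logical vector over the input) and
#'   `n_removed`.
#' @export
truncate_distances <- function(distances, percentile = 98) {
  if (length(distances) < 20) stop("need at least 20 distances to truncate")
  w <- as.numeric(stats::quantile(distances, percentile / 100, type = 7))
  keep <- distances <= w
  list(w = w, keep = keep, n_removed = sum(!keep))
}

# key function values; b ignored for the half-normal
detection_g <- function(x, sigma, key, b = NULL) {
  if (key == "hn") {
    exp(-x^2 / (2 * sigma^2))
  } else if (key == "hr") {
    g <- 1 - exp(-(x / sigma)^(-b))
    g[x == 0] <- 1
    g
  } else stop("unknown key: ", key)
}

# closed-form half-normal integral of g over [0, w]:
# sigma * sqrt(pi/2) * erf(w / (sigma * sqrt(2)))
hn_esw_closed <- function(sigma, w) {
  sigma * sqrt(pi / 2) * pracma::erf(w / (sigma * sqrt(2)))
}

# design matrix for the scale model (intercept + requested covariates)
detection_design <- function(data, covariates) {
  Z <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (!cv %in% names(data)) stop("covariate not in data: ", cv)
    Z <- cbind(Z, as.numeric(data[[cv]]))
    colnames(Z)[ncol(Z)] <- cv
  }
  Z
}

#' Fit a detection function by maximum conditional likelihood
#'
#' Maximises the conditional line-transect likelihood
#' `prod_i g(x_i; sigma_i) / mu_i` with `mu_i = int_0^w g(u; sigma_i) du`,
#' where `sigma_i = exp(beta0 + beta' z_i)`. The half-normal integral
#' uses its error-function closed form; the hazard-rate integral uses
#' fixed 61-node Gauss-Legendre quadrature on [0, w], vectorised over
#' observations. The hazard-rate shape is parameterised as `log b` so
#' `b > 0` always holds.
#'
#' @param data data frame with `distance_m` (already truncated at `w`)
#'   and any covariate columns named in `covariates`.
#' @param key `"hn"` (half-normal) or `"hr"` (hazard-rate).
#' @param covariates character vector of scale covariates (subset of the
#'   columns of `data`, e.g. `c("bss", "sightability")`); empty for a
#'   covariate-free fit.
#' @param w truncation distance in m.
#' @return object of class `detection_model`: list with `key`,
#'   `covariates`, `beta` (scale coefficients, log link), `b` (shape,
#'   hazard-rate only), `sigma0_m = exp(beta0)`, `logL`, `AIC`, `npar`,
#'   `w`, `n`.
#' @export
fit_detection <- function(data, key = c("hn", "hr"), covariates = character(),
                          w) {
  key <- match.arg(key)
  x <- data$distance_m
  if (any(x < 0)) stop("negative perpendicular distance")
  if (any(x > w)) stop("distances must be truncated at w before fitting")
  Z <- detection_design(data, covariates)
  p_scale <- ncol(Z)
  if (key == "hr") {
    gl <- pracma::gaussLegendre(61, 0, w)
    nodes <- gl$x; wts <- gl$w
  }
  negll <- function(par) {
    beta <- par[seq_len(p_scale)]
    sigma <- exp(pmin(drop(Z %*% beta), 20))
    if (key == "hn") {
      mu <- hn_esw_closed(sigma, w)
      ll <- -x^2 / (2 * sigma^2) - log(mu)
    } else {
      b <- exp(par[p_scale + 1])
      G <- 1 - exp(-outer(1 / sigma, nodes, "*")^(-b))
      mu <- drop(G %*% wts)
      gx <- detection_g(x, sigma, "hr", b)
      # reject regions where g underflows (e.g. sigma -> 0, where the
      # floored ratio g/mu would look spuriously perfect)
      if (any(!is.finite(mu)) || any(mu <= 1e-10) ||
          any(!is.finite(gx)) || any(gx <= 1e-12)) return(1e10)
      ll <- log(gx) - log(mu)
    }
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }
  start <- c(log(sqrt(mean(x^2)) + 1e-6), rep(0, p_scale - 1))
  if (key == "hr") start <- c(start, log(2.5))
  fit <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (fit$convergence != 0) {
    fit2 <- stats::optim(fit$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000))
    if (fit2$value <= fit$value) fit <- fit2
    if (fit$convergence != 0) {
      stop("detection fit did not converge (code ", fit$convergence,
           ", key ", key, ", nll ", signif(fit$value, 6), ")")
    }
  }
  beta <- fit$par[seq_len(p_scale)]
  names(beta) <- colnames(Z)
  npar <- p_scale + (key == "hr")
  structure(list(
    key = key,
    covariates = covariates,
    beta = beta,
    b = if (key == "hr") exp(fit$par[p_scale + 1]) else NULL,
    sigma0_m = exp(beta[[1]]),
    logL = -fit$value,
    AIC = 2 * fit$value + 2 * npar,
    npar = npar,
    w = w,
    n = length(x)
  ), class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model> key=%s covariates=[%s]\n", x$key,
              paste(x$covariates, collapse = ", ")))
  cat(sprintf("  sigma0 = %.1f m%s, w = %.1f m, n = %d\n", x$sigma0_m,
              if (!is.null(x$b)) sprintf(", shape b = %.2f", x$b) else "",
              x$w, x$n))
  cat(sprintf("  logL = %.2f, AIC = %.2f (%d parameters)\n",
              x$logL, x$AIC, x$npar))
  invisible(x)
}

# per-observation detection scale under a fitted model
detection_sigma <- function(model, newdata = NULL) {
  if (is.null(newdata) || length(model$covariates) == 0) {
    n <- if (is.null(newdata)) 1L else nrow(newdata)
    return(rep(exp(model$beta[[1]]), n))
  }
  Z <- detection_design(newdata, model$covariates)
  exp(pmin(drop(Z %*% model$beta), 20))
}

#' Fit the candidate detection-function set
#'
#' Fits every combination of key (half-normal, hazard-rate) and
#' covariate subset (none, BSS, sightability, both) to the same
#' truncated data. Candidates that fail to converge are dropped with a
#' warning.
#'
#' @param data truncated distance data (see [fit_detection()]).
#' @param w truncation distance in m.
#' @param keys keys to try.
#' @param covariate_sets list of covariate subsets to try.
#' @return list of `detection_model` objects.
#' @export
fit_detection_candidates <- function(data, w, keys = c("hn", "hr"),
                                     covariate_sets = list(
                                       character(), "bss", "sightability",
                                       c("bss", "sightability"))) {
  out <- list()
  for (key in keys) {
    for (cv in covariate_sets) {
      label <- paste0(key, if (length(cv)) paste0("+", paste(cv, collapse = "+")))
      m <- tryCatch(fit_detection(data, key, cv, w), error = function(e) {
        warning("candidate ", label, " failed: ", conditionMessage(e))
        NULL
      })
      if (!is.null(m)) out[[label]] <- m
    }
  }
  out
}

#' Select a detection model by AIC
#'
#' Returns the minimum-AIC candidate; exact ties are broken toward the
#' model with fewer parameters.
#'
#' @param candidates list of `detection_model` objects on identical data.
#' @return the selected `detection_model`.
#' @export
select_detection <- function(candidates) {
  candidates <- Filter(Negate(is.null), candidates)
  if (length(candidates) == 0) stop("no converged detection candidates")
  aic <- vapply(candidates, `[[`, numeric(1), "AIC")
  npar <- vapply(candidates, `[[`, numeric(1), "npar")
  best <- which(aic == min(aic))
  if (length(best) > 1) best <- best[which.min(npar[best])]
  candidates[[best]]
}

#' Effective strip width
#'
#' `ESW = int_0^w g(x; sigma(z)) dx`, evaluated by adaptive quadrature
#' with absolute tolerance `1e-6 * w`. For covariate models, supply the
#' covariate values (e.g. segment mean conditions) in `newdata`; the
#' integral is evaluated once per unique scale value.
#'
#' @param model a fitted `detection_model`.
#' @param newdata data frame of covariate values (NULL for the baseline).
#' @return ESW in m, one value per row of `newdata` (or a single value).
#' @export
esw <- function(model, newdata = NULL) {
  sigma <- detection_sigma(model, newdata)
  us <- unique(sigma)
  vals <- vapply(us, function(s) {
    stats::integrate(function(u) detection_g(u, s, model$key, model$b),
                     0, model$w, abs.tol = 1e-6 * model$w,
                     subdivisions = 200L)$value
  }, numeric(1))
  vals[match(sigma, us)]
}
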