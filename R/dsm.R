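# Stock-specific density surface models: quasi-Poisson generalized
# additive models of per-segment porpoise counts on habitat covariates,
# with the effective-area offset log(2 * esw * length) and shrinkage
# term selection.
#
# Each 1-D habitat term is a penalized cubic regression spline with
# basis dimension k = 5; the upwelling term is a 2-D thin plate
# regression spline of (cumulative CUTI, cumulative relaxation) with
# basis dimension k = 15; substrate enters as a parametric two-level
# factor (soft as reference). Smoothing parameters are chosen by REML by
# default. Variable selection uses shrinkage smoothers: each basis
# carries a penalty that also shrinks the penalty null space, so a term
# with no support in the data is estimated as (near) zero everywhere.
# mgcv offers two equivalent routes to this (shrinkage bases "cs"/"ts",
# or the double penalty via select = TRUE); the shrinkage bases are the
# default here because the approximate term-wise p-values are better
# calibrated under them.

default_smooth_terms <- c("depth", "dist_coast", "shelf_width", "dist_cape",
                          "dist_estuary", "sst")

#' Fit a density surface model for one stock
#'
#' @param segments a `survey_segments` table (one stock's rows, or pass
#'   `stock` to subset).
#' @param stock optional stock label to subset `segments`.
#' @param smooth_terms 1-D smooth terms to include (default: depth,
#'   distance to coast, shelf width, distance to cape, distance to
#'   estuary, SST).
#' @param drop_terms terms to omit, e.g. `"dist_cape"` for a stock range
#'   where prominent capes are scarce and the covariate would invite
#'   spurious inference.
#' @param k_smooth basis dimension for 1-D smooths (default 5).
#' @param k_interaction basis dimension for the 2-D upwelling x
#'   relaxation interaction (default 15).
#' @param method smoothing-parameter criterion (default `"REML"`;
#'   `"GCV.Cp"` available).
#' @param select add mgcv's double penalty on top of the shrinkage
#'   bases (default FALSE; the bases already shrink their null spaces).
#' @param include_interaction include the 2-D upwelling x relaxation
#'   smooth (default TRUE; FALSE gives reduced models, down to
#'   intercept-only when `smooth_terms` is empty).
#' @return object of class `dsm_fit`: list with the fitted `gam`, the
#'   `stock` label, `terms` used, `dispersion` (Pearson estimate),
#'   `deviance_explained` (percent), and the training dynamic-covariate
#'   table used as the ExDet reference.
#' @export
fit_dsm <- function(segments, stock = NULL,
                    smooth_terms = default_smooth_terms,
                    drop_terms = NULL, k_smooth = 5, k_interaction = 15,
                    method = "REML", select = FALSE,
                    include_interaction = TRUE) {
  dat <- as.data.frame(segments)
  if (!is.null(stock)) dat <- dat[dat$stock == stock, ]
  if (nrow(dat) == 0) stop("no segments to fit")
  terms <- setdiff(smooth_terms, drop_terms)
  usable <- character(0)
  for (tm in terms) {
    v <- dat[[tm]]
    if (is.null(v) || all(is.na(v))) {
      warning("term ", tm, " absent; omitted")
    } else if (length(unique(v)) <= k_smooth) {
      warning("term ", tm, " has too few unique values; omitted")
    } else usable <- c(usable, tm)
  }
  parametric <- character(0)
  if ("substrate" %in% names(dat) && !all(is.na(dat$substrate))) {
    dat$substrate <- factor(dat$substrate, levels = c("soft", "hard"))
    if (nlevels(droplevels(dat$substrate)) == 2) {
      parametric <- "substrate"
    } else {
      warning("substrate has a single level; omitted")
    }
  }
  rhs <- c(
    sprintf("s(%s, k = %d, bs = \"cs\")", usable, k_smooth),
    if (include_interaction)
      sprintf("s(cumulative_cuti, cumulative_relaxation, k = %d, bs = \"ts\")",
              k_interaction),
    parametric,
    "offset(log(offset_area))")
  if (length(rhs) == 1) rhs <- c("1", rhs)
  form <- stats::reformulate(rhs, response = "n_porpoises")
  g <- mgcv::gam(form, family = stats::quasipoisson(link = "log"),
                 data = dat, method = method, select = select)
  smry <- summary(g)
  structure(list(
    gam = g,
    stock = if (is.null(stock)) unique(dat$stock) else stock,
    smooth_terms = usable,
    parametric_terms = parametric,
    dispersion = smry$dispersion,
    deviance_explained = 100 * smry$dev.expl,
    summary = smry,
    has_interaction = include_interaction,
    reference_dynamic = dat[intersect(
      c("cumulative_cuti", "cumulative_relaxation", "sst"), names(dat))],
    data = dat
  ), class = "dsm_fit")
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat(sprintf("<dsm_fit> stock=%s, n=%d segments\n",
              paste(x$stock, collapse = "/"), nrow(x$data)))
  cat(sprintf("  deviance explained = %.1f%%, dispersion = %.2f\n",
              x$deviance_explained, x$dispersion))
  print(term_significance(x))
  invisible(x)
}

#' Approximate per-term significance
#'
#' Approximate Wald-type tests for each smooth and an F test for the
#' parametric substrate term, both using the quasi-likelihood Pearson
#' dispersion (mgcv's `summary.gam` machinery).
#'
#' @param fit a `dsm_fit`.
#' @return data frame with `term`, `type`, `edf` (smooths), `p_value`.
#' @export
term_significance <- function(fit) {
  s <- fit$summary
  out <- data.frame(term = rownames(s$s.table), type = "smooth",
                    edf = s$s.table[, "edf"],
                    p_value = s$s.table[, "p-value"])
  if (!is.null(s$pTerms.table) && nrow(s$pTerms.table) > 0) {
    out <- rbind(out, data.frame(term = rownames(s$pTerms.table),
                                 type = "parametric", edf = NA_real_,
                                 p_value = s$pTerms.table[, "p-value"]))
  }
  rownames(out) <- NULL
  out
}

#' Per-term contributions to the linear predictor
#'
#' Evaluates each model term's contribution on the link scale at the
#' supplied covariate rows. The returned matrix plus the intercept and
#' the log-area offset reconstructs the full linear predictor.
#'
#' @param fit a `dsm_fit`.
#' @param newdata covariate rows (default: the training segments).
#' @return matrix of term contributions with attribute `"constant"`
#'   (the intercept).
#' @export
linear_predictor_terms <- function(fit, newdata = NULL) {
  if (is.null(newdata)) newdata <- fit$data
  tm <- stats::predict(fit$gam, newdata = newdata, type = "terms")
  attr(tm, "constant") <- attr(tm, "constant") %||% stats::coef(fit$gam)[1]
  tm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partial-effect curves and surfaces
#'
#' Evaluates each 1-D smooth over a grid spanning its observed range
#' (other covariates held at their medians, substrate at the reference
#' level) and the 2-D upwelling x relaxation smooth over a lattice, with
#' lattice cells masked when no training segment lies nearby (conditions
#' that never occurred in the data are not displayed).
#'
#' @param fit a `dsm_fit`.
#' @param n grid size per dimension (default 100 for curves, 40 for the
#'   surface).
#' @param mask_distance for the 2-D surface, a lattice cell is masked
#'   when the nearest training point (covariates scaled to [0,1]) is
#'   farther than this fraction of the range (default 0.1).
#' @return named list: for each 1-D term a data frame `value`, `effect`;
#'   for the interaction a data frame `cumulative_cuti`,
#'   `cumulative_relaxation`, `effect`, `masked`.
#' @export
partial_effects <- function(fit, n = 100, mask_distance = 0.1) {
  dat <- fit$data
  base <- dat[1, , drop = FALSE]
  covs <- c(fit$smooth_terms,
            if (fit$has_interaction) c("cumulative_cuti", "cumulative_relaxation"))
  for (tm in covs) {
    base[[tm]] <- stats::median(dat[[tm]], na.rm = TRUE)
  }
  if (length(fit$parametric_terms)) {
    base$substrate <- factor("soft", levels = levels(dat$substrate))
  }
  base$offset_area <- 1
  out <- list()
  for (tm in fit$smooth_terms) {
    rng <- range(dat[[tm]], na.rm = TRUE)
    nd <- base[rep(1, n), , drop = FALSE]
    nd[[tm]] <- seq(rng[1], rng[2], length.out = n)
    tmat <- stats::predict(fit$gam, newdata = nd, type = "terms")
    col <- grep(sprintf("s\\(%s\\)", tm), colnames(tmat))
    out[[tm]] <- data.frame(value = nd[[tm]], effect = tmat[, col])
  }
  if (!fit$has_interaction) return(out)
  ng <- min(n, 40)
  r1 <- range(dat$cumulative_cuti); r2 <- range(dat$cumulative_relaxation)
  gg <- expand.grid(
    cumulative_cuti = seq(r1[1], r1[2], length.out = ng),
    cumulative_relaxation = seq(r2[1], r2[2], length.out = ng))
  nd <- base[rep(1, nrow(gg)), , drop = FALSE]
  nd$cumulative_cuti <- gg$cumulative_cuti
  nd$cumulative_relaxation <- gg$cumulative_relaxation
  tmat <- stats::predict(fit$gam, newdata = nd, type = "terms")
  col <- grep("cumulative_cuti,cumulative_relaxation", colnames(tmat))
  sc1 <- diff(r1) + 1e-12; sc2 <- diff(r2) + 1e-12
  d2 <- outer((gg$cumulative_cuti) / sc1, dat$cumulative_cuti / sc1, "-")^2 +
    outer((gg$cumulative_relaxation) / sc2, dat$cumulative_relaxation / sc2, "-")^2
  nearest <- sqrt(apply(d2, 1, min))
  out[["cumulative_cuti:cumulative_relaxation"]] <- data.frame(
    gg, effect = tmat[, col], masked = nearest > mask_distance)
  out
}

#' Deviance explained by a fitted DSM
#'
#' @param fit a `dsm_fit`.
#' @return percent deviance explained, `100 * (1 - deviance/null deviance)`.
#' @export
deviance_explained <- function(fit) fit$deviance_explained
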