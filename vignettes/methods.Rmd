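---
title: "Methods: nearshore density surface modelling with upwelling phenology"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `porpoisedsm`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one reasonable option
existed.

## The two-stage density surface model

Line-transect distance sampling corrects counts for imperfect
detection: the probability of detecting a porpoise group declines with
perpendicular distance $x$ from the trackline, described by a detection
function $g(x)$ with $g(0) = 1$. Two keys are supported:

* half-normal: $g(x) = \exp(-x^2 / 2\sigma^2)$
* hazard-rate: $g(x) = 1 - \exp(-(x/\sigma)^{-b})$, $b > 0$

Observation conditions (Beaufort sea state, an ordinal sightability
score) act on the scale through a log link,
$\sigma_i = \exp(\beta_0 + \beta^\top z_i)$ — the standard
multiple-covariate distance sampling formulation; the hazard-rate shape
$b$ is shared across covariate levels. Parameters maximize the
conditional likelihood $\prod_i g(x_i;\sigma_i)/\mu_i$ with
$\mu_i = \int_0^w g(u;\sigma_i)\,du$, after truncation at the 98th
percentile of observed distances (type-7 quantile: linear interpolation
between order statistics). Candidate models (2 keys × 4 covariate sets)
are compared by AIC with ties broken toward fewer parameters. The
effective strip width $\mathrm{ESW} = \int_0^w g$ is evaluated by
adaptive quadrature to an absolute tolerance of $10^{-6} w$; for the
half-normal it equals $\sigma\sqrt{\pi/2}\,
\mathrm{erf}(w/\sigma\sqrt2)$, which the tests use as an independent
check. Availability and perception bias are assumed absent or constant;
no $g(0) < 1$ correction is applied, so absolute abundance may be
underestimated by a constant factor while trends are unaffected.

The second stage sums individuals and averages conditions per survey
segment and models per-segment counts with a quasi-Poisson GAM
(log link, variance $\phi\mu$):

* 1-D shrinkage smooths (basis dimension $k = 5$) of depth, distance to
  coast, shelf width, signed distance to cape, distance to estuary, and
  SST;
* a 2-D thin-plate shrinkage smooth ($k = 15$) of cumulative upwelling
  × cumulative relaxation;
* substrate as a parametric two-level factor (soft reference);
* offset $\log(2\,(\mathrm{ESW}/1000)\,\mathrm{length})$, the effective
  area in km², which also absorbs segment-length variation.

Smoothing parameters are selected by REML (GCV available). For stock
ranges where prominent capes are scarce the cape covariate is omitted
(`drop_terms = "dist_cape"`) to avoid spurious inference from a
long-range distance gradient.

**Shrinkage construction.** Term selection uses shrinkage smoothers:
the penalty is modified so that the smoother's null space is also
penalized, letting unsupported terms shrink to zero rather than to a
straight line. mgcv implements this either through shrinkage bases
(`bs = "cs"`/`"ts"`) or through a double penalty (`select = TRUE`);
both descend from the same selection approach. The shrinkage bases are
the default here because, in repeated simulations with a pure-noise
covariate at $n = 3000$ segments, the approximate term-wise p-values
were close to nominal under the bases (noise term non-significant at
the 5% level in ≈94% of replicates) but anti-conservative under the
double penalty (≈84%). `select = TRUE` remains available.

## Static covariates

Computed at 1 km resolution on a local planar projection (km), with a
linear mapping of northing to latitude — at the 1–5 km scales of this
design the planar error is negligible, and it keeps every geometric
operation exactly testable:

* **Depth** and **substrate** come from the world's grids.
* **Distance to coast**: Euclidean distance to the coastline polyline.
* **Shelf width**: shortest distance from the coast to the 200 m
  isobath, one value per latitude row broadcast across longitudes;
  the isobath crossing is located by linear interpolation between cell
  centres; rows whose isobath lies outside the grid are flagged missing
  and their segments dropped from fitting with a warning.
* **Capes**: the coastline is smoothed with a 200 km arc-length
  centred moving average of vertex positions (the simplest smoother
  with a window in km; endpoints use the truncated window, and the
  smoothed polyline is extended along its end tangents before offsets
  are measured, so domain ends are not mistaken for excursions).
  Contiguous runs of vertices more than 5 km from the smooth are merged
  into one cape at the maximum-offset vertex. Signed distance to the
  nearest cape is negative north of it and positive south, by latitude
  comparison only. Straight-line (not along-coast) distance is used;
  the choice is configurable in principle but straight-line matches the
  planar design.
* **Estuaries**: Euclidean distance to the nearest estuary with area
  strictly greater than 300 ha (small creeks excluded).

## Upwelling phenology and dynamic covariates

Daily upwelling-index series per 1° latitude bin are smoothed with a
10-day running mean (centred; a symmetric window avoids phase lag in
the spring transition; edges use the available sub-window; for the even
window the centre reaches 4 days back and 5 forward). Per year and bin,
the smoothed series is accumulated from 1 January; the **spring
transition (STI)** is the day of the cumulative minimum and the season
**END** — reported also as **MAX**, the day of maximum upwelling
accumulation, since both use the cumulative maximum — is the day of the
cumulative maximum. **TUMI** is the cumulative upwelling re-accumulated
from the STI and evaluated at END; **LUSI** = END − STI. Years with the
maximum before the minimum are flagged degenerate and excluded.

The **relaxation threshold** per bin is the mean smoothed index over
all in-season days pooled across all study years (the smoothed series
is used throughout; the raw series never feeds the model). A
**relaxation event** is an in-season day strictly below the threshold;
**cumulative relaxation** counts such days since the STI, and
**cumulative CUTI** re-accumulates the smoothed index from the STI
(zero on and before it, continuing past END through the prediction
window). Stock-level annual phenology averages, unweighted, the bins
whose 1° interval intersects the stock's latitude range; partially
overlapping bins count fully. Leap days are kept; day-of-year is the
calendar day index.

## Prediction, extrapolation filtering, anomalies

Daily predictions run over a grid of 5 km alongshore cells spanning the
coast-to-5 km strip (cell area is the exact alongshore × cross-shore
product; the strip is entirely seaward so no land clipping arises),
from 15 May to 30 August inclusive. Predicted abundance per cell is
area × exp(linear predictor with the log-area offset); density is
abundance/area.

Days with non-analog **dynamic** conditions are excluded with the ExDet
statistic computed against the fitting segments' dynamic covariates
(cumulative CUTI, cumulative relaxation, SST) — static covariates are
inside the surveyed envelope by construction. For a point $x$,
$\mathrm{NT1} = \sum_j \min(x_j - \min_j, \max_j - x_j, 0) /
(\max_j - \min_j)$; negative NT1 (univariate range extrapolation) is
returned directly, otherwise NT2 is the squared Mahalanobis distance
from the reference mean divided by the maximum squared reference
Mahalanobis distance, flagging novel covariate combinations when > 1.
A day is dropped when any cell scores > 1.15 or < −0.15; the rule is
exact set logic with no tolerance.

Annual series are means of daily study-area totals over retained days;
a year with no retained day propagates as missing. Per-stock
**density anomalies** are z-scores of the annual mean densities
(sample SD; zero variance raises an error by contract). Uncertainty is
by coefficient simulation from the asymptotic sampling distribution of
the GAM coefficients (eigen-decomposition draws, so rank-deficient
covariances are tolerated); CV = SD/mean of re-predicted abundance,
per cell and per grouped total, with the annual CV taken as the mean of
daily CVs. Detection-function uncertainty is not propagated — the CV
reflects the spatial-model stage only.

Trend models regress anomalies on each phenology index and on spring
(February–May) means of monthly climate indices, with stock as a factor
and a stock × index interaction; effects are assessed by sequential
ANOVA with the index entered first, and per-stock slopes combine the
index coefficient with the interaction contrasts (verified against
separate per-stock regressions). PDO/MEI-like indices are treated as a
single basin-scale series shared across stocks.

## The synthetic world: what it emulates, and what it does not

`generate_world()` builds, from a configuration and a seed (all
generators are pure functions of both):

* a north–south coastline with Gaussian promontories (default 8 km
  seaward, detectable capes), a linearly sloping shelf whose slope is
  modulated alongshore so shelf width varies by latitude, estuaries
  with log-normal areas around 500 ha, and substrate that is hard near
  capes plus random speckle;
* daily upwelling series per bin: winter baseline −0.4 m²/s rising to
  a summer amplitude ≈1.2 m²/s between a spring onset (mean day 100,
  SD 18 d, 20 d ramp) and a fall collapse (mean day 280, SD 5 d, 8 d
  ramp), plus AR(1) noise. Inter-annual variation in season length is
  thus driven mainly by onset timing with an abrupt fall transition —
  the pattern of real eastern-boundary upwelling systems — which makes
  the season-length index a genuine driver of in-season cumulative
  upwelling, the quantity the density surface responds to;
* SST per bin: seasonal cycle, cooling proportional to smoothed
  upwelling, a latitudinal gradient, daily noise;
* a true detection function (default covariate-free half-normal,
  σ = 100 m) and a true group-density surface: log-quadratic in depth
  (optimum 15 m — the observed shallow-water preference) and log-linear
  in cumulative upwelling, with zero-truncated Poisson group sizes of
  mean 1.46 individuals (the ratio of individuals to observations in
  long-running nearshore surveys).

Surveys follow the Marbled Murrelet monitoring design the historical
data inherit: 20 km PSUs; four 5 km inshore segments per PSU at
independent uniform offsets < 1.5 km from shore (northern design;
< 2 km southern), one 5 km diagonal offshore transect from the inshore
boundary to 5 km (north) or 3 km (south) with a randomized alongshore
start (the diagonal's bearing is fixed by requiring a 5 km segment
between the two boundaries; the historical design does not state it).
The number of sampling occasions per PSU per year is open in the
historical record and is exposed as configuration (default 4).
Observation conditions are drawn as ordinal categories (BSS 0–5,
sightability 1–5) with configurable marginals; the field protocol
records them continuously but publishes no distribution.

Not emulated: real coastline geometry, tides and currents, seabird
observations, availability/perception bias, observer heterogeneity,
inter-annual redistribution between inshore and offshore waters. A
passing recovery suite therefore demonstrates that the estimation chain
is self-consistent — unbiased under its own assumptions — not that
those assumptions hold for any particular field dataset.

## Numerical choices and degenerate inputs

* Hazard-rate integrals use fixed 61-node Gauss–Legendre quadrature on
  [0, w], vectorized over observations; half-normal integrals use the
  error-function closed form. Optimization is BFGS with a Nelder–Mead
  fallback; the shape is parameterized as $\log b$ so $b > 0$ always.
  Parameter regions where $g$ underflows are rejected (an underflowing
  ratio $g/\mu$ would otherwise masquerade as a perfect fit at
  $\sigma \to 0$).
* ESW quadrature: `stats::integrate`, absolute tolerance $10^{-6} w$,
  evaluated once per unique scale value.
* Stock assignment: a centroid exactly on a shared boundary goes to the
  southern stock. Encounter-rate strata with no effort are emitted as
  missing (distinct from surveyed-but-empty, which is 0); strata with
  < 1 km effort are flagged unstable. The encounter-rate latitude bin
  width is a parameter (default 0.1°; 1° used for coarse maps).
* Segments or grid cells with missing covariates (land, no isobath) are
  dropped with warnings rather than imputed.
* Partial-effect surfaces mask lattice cells with no nearby observed
  covariate combination (nearest-neighbour distance in range-scaled
  units > 0.1), so effects are only displayed where conditions occurred.
* The problem sizes used by the test and acceptance runs — a 200 km
  coast, two stocks, five years, four occasions per PSU per year,
  ~1000 segments, a 40-cell prediction grid — were chosen as the
  smallest configuration in which every stage (including ExDet
  filtering and the anomaly regressions) operates away from its edge
  cases; all scale up by configuration.

## Known limitations

* The conditional detection likelihood ignores effort without
  sightings by construction; absolute density enters only through the
  offset, so detection-parameter uncertainty is not propagated into
  prediction CVs.
* Quasi-likelihood has no AIC, so DSM term retention relies entirely on
  shrinkage, and term-wise p-values are approximate.
* Sequential (type-I) ANOVA is the default for trend models (index
  first); with the balanced synthetic designs the distinction from
  type-II is minor, but both orderings are available by refitting.
* No spatial or temporal autocorrelation structure is modelled in
  either the DSM or the trend regressions.
* SST is generated and extracted at latitude-bin resolution, emulating
  a coarse optimally interpolated product rather than km-scale fields.
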