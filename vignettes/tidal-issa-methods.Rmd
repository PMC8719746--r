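---
title: "Methods: step selection under tidal water-depth dynamics"
author: "tidalissa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step selection under tidal water-depth dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidalissa)
```

## The problem

Wading birds foraging in an estuary experience a landscape whose usability
changes hour by hour: a mudflat that is ideal at mid-tide is dry at low
tide and too deep at high tide. `tidalissa` implements an analysis chain
for GPS/accelerometer-tagged birds in such landscapes. Its scientific core
is an integrated step-selection analysis (iSSA): habitat selection and
movement are estimated jointly by comparing each observed movement step
against "available" steps sampled from the animal's own movement kernel,
via conditional logistic regression. Around that core sit the covariate
engine (wetland class, elevation, tide, time-specific water depth), track
filtering, an energy-expenditure index from accelerometry (ODBA), and a
mixed-model comparison of ODBA across wetland types.

## Covariate engine

**Wetland raster.** Three vector layers are overlaid onto a square grid
(default cell size 10 m): a base layer of classed polygons (`tidal_marsh`,
`other_tidal`, `excluded`), an eelgrass polygon layer, and a shellfish
aquaculture layer of polygons and gear lines. A cell takes the class of
the layer covering its *centre*, with precedence shellfish > eelgrass >
base. The centre rule is deterministic and appropriate at the 10 m scale;
the precedence order reflects that aquaculture infrastructure physically
overlies vegetation. Buffers mirror how such layers are digitised:
eelgrass is dilated by 5 m (closing gaps between adjacent patches),
shellfish gear lines are treated as 1 m-buffered runs with a further 1 m
closing dilation of the merged shape. Because the rasterization rule only
ever asks whether a *buffered geometry covers a point*, dilation is
implemented exactly as a distance threshold (point-to-geometry distance
≤ buffer radius); no polygon offsetting is needed. All geometry is
assumed pre-projected to a planar metric CRS; the package never
reprojects, and declared geographic CRSs are rejected at read time.

**Elevation.** A DEM and a bathymetry grid sharing the raster geometry are
merged: the DEM wins at or above a cutoff (default 0 m, the tide datum),
bathymetry below it, since LiDAR-derived DEMs are unreliable under water.
Vertical datums are treated as equal; for the region this package was
designed around, the relevant datums differ by under a centimetre.

**Tide.** Hourly predicted heights at a reference station, optionally
shifted by additive time and height offsets for a subordinate station
(applied to the knots before interpolation; published subordinate-station
corrections are usually stated in exactly this additive form, and a
multiplicative height ratio would be a one-line change). Interpolation
between knots uses a shape-preserving piecewise cubic (PCHIP:
Fritsch-Carlson slopes, zeroed at local extrema). We implemented PCHIP
directly because the monotone spline in base R can overshoot the
bracketing knots by a few centimetres near high and low water, and the
interpolant here must never invent water that the prediction does not
contain. The price of shape preservation is a flattened extremum: for a
sinusoidal constituent of amplitude $A$ sampled hourly with period $T$,
*any* interpolant bounded by its bracketing knots must miss the true peak
by up to $A(1-\cos(\pi h/T))$ — about 3 cm for a 1 m semidiurnal
constituent. At hourly spacing this is far below tidal amplitude and
below the vertical uncertainty of the elevation data. No extrapolation is
permitted outside the series span.

**Water depth.** `depth(x, y, t) = tide(t) - elevation(cell(x, y))`,
in metres; negative values are heights above the waterline. The value is
a cell-average quantity at raster resolution, not the depth under the
bird's feet; inference inherits that scale.

## Track preparation

Fixes are filtered to tag accuracy < 10 m, daylight, and tag speed
≤ 5 m s⁻¹ (the boundary is inclusive; the cut excludes
flight, which is several times faster than any foraging movement).
Daylight is defined as solar elevation ≥ 0° computed by the
standard NOAA solar-position formulas at a configured reference
coordinate; a civil-twilight variant is available by setting
`min_solar_elevation = -6`. Tracks are then regularised to a 10-min
interval (tolerance ±60 s, one fifth of a 5-min native interval) by
a greedy walk; gaps beyond tolerance start a new segment and segments
shorter than three fixes are dropped, because a turn angle needs three
points. Steps carry length, signed turn angle (counterclockwise positive,
in $(-\pi, \pi]$, with reversals mapped to $+\pi$), and the previous
heading. A step whose previous displacement has zero length cannot anchor
available steps and is flagged; its length still informs the step-length
kernel.

## The estimator

**Tentative kernel.** Per bird, a gamma distribution is fitted to all
observed step lengths by maximum likelihood (zero lengths are floored at
half the minimum positive length, with a message) and a mean-zero von
Mises distribution to the defined turn angles (concentration solved from
the Bessel-function ratio $A_1(\kappa) = \overline{\cos\theta}$, capped
at 500 for near-degenerate samples). Kernels are fitted *before* any
covariate-based exclusion so they describe raw movement.

**Strata.** Each observed step is paired with `n_avail = 10` available
steps drawn from the tentative kernel and projected from the observed
start point and previous heading. End-of-step covariates (wetland class,
time-specific depth) are attached; members landing off-grid or in
excluded cells are removed. The analysis window restricts end-of-step
depths to $[-0.5, 1]$ m — beyond 1 m the cell-average depth exceeds
wading range, and sites more than 0.5 m above the waterline are excluded
because shellfish infrastructure barely occurs there, which would
otherwise confound the class contrast with pure elevation. The window is
applied to observed and available members alike (the likelihood then
conditions on the restricted choice set, which keeps the estimator
consistent); a stratum losing its observed member or all available
members is dropped.

**Conditional logistic fit.** The stratified conditional log partial
likelihood
$$\ell(\beta) = \sum_s \Big[ x_{s,\text{used}}^\top \beta -
  \log \sum_{j \in s} \exp(x_{s,j}^\top \beta) \Big]$$
is maximised by Newton-Raphson with analytic gradient and Hessian and
step-halving, so iterations never decrease $\ell$. Convergence requires a
relative $\ell$ change below $10^{-9}$ and a maximum score component
below $10^{-6}$, within 100 iterations. Covariates constant within every
stratum do not enter the likelihood; they are flagged unidentifiable and
excluded rather than silently returned. Separation — a covariate pattern
driving a coefficient to infinity, as happens for a bird that almost
never enters one wetland class — is detected as any $|\hat\beta| > 15$
*at the final iterate* (transient Newton overshoots are not grounds for
exclusion; this distinction matters in practice) or a non-finite or
singular information matrix; such fits are reported but marked
non-converged and excluded from pooled inference. The covariance is the
inverse observed information.

**Candidate set and ranking.** Seven models: wetland alone, depth alone,
depth + depth², their additive combinations, wetland × depth,
and the full wetland × (depth + depth²) interaction. Ranking is
by AICc with $n$ = number of strata, ties broken toward fewer
parameters; Akaike weights are reported. Only converged fits enter the
ranking.

**Relative selection strength.** For the best model, log-RSS of class $w$
versus the `other_tidal` reference at depth $d$ is the design-row
contrast $x(w,d)^\top\beta - x(\text{ref},d)^\top\beta$, with 95%
delta-method (Wald) intervals from the fit covariance. Profile intervals
were considered and deferred; at the stratum counts involved the two are
close for contrast terms.

**Movement model and corrected kernels.** Appending per-wetland-start
step-length and log-step-length columns to the best model and refitting
yields coefficients that repair the tentative kernel class by class:
$\text{shape}' = \text{shape} + \beta_{\ln sl}$ and
$1/\text{scale}' = 1/\text{scale} - \beta_{sl}$ (an error if the
corrected rate is non-positive, naming the class). We code the movement
terms per class (four `sl_*`, four `log_sl_*` columns, no main effect)
rather than main-plus-interaction: the fit space is identical and the
correction reads off one coefficient pair per class. Turn angles are not
corrected.

**Per-bird fitting.** Models are fitted to each bird separately; no
pooled random-effects conditional model is attempted. Pooling across
birds, where needed for validation, uses inverse-variance weighting of
per-bird estimates.

## ODBA and the mixed model

ODBA per 6 s, 10 Hz burst is the sum over the three axes of absolute
deviations from each axis's whole-burst mean — a sum over the burst, in
raw acceleration units, invariant to per-axis offsets (gravity and tag
orientation) and homogeneous of degree one in scale. The whole-burst
mean is the static-acceleration estimate; no running mean or gravity
rotation is applied. Bursts shorter than 60 samples are processed with a
`partial` flag; below 10 samples they are rejected. ODBA records enter
the behavioural model at the native 5-min interval, filtered by the same
accuracy/daylight/speed rules as fixes but *not* by the depth window,
which belongs to the selection analysis only.

The behavioural model is `odba ~ wetland + (1 | bird_id)`, fitted by
maximum likelihood (not REML, since nested fixed-effect structures are
compared) via `lme4`, with treatment coding against `other_tidal`. The
wetland effect is tested against an intercept-only null with a
likelihood-ratio test on 3 degrees of freedom. Fixed-effect intervals are
profile-likelihood by default with a logged Wald fallback. Degenerate
designs error out rather than returning arbitrary variance splits: a
single bird, or one observation per bird (random-intercept and residual
variances confounded). With only a handful of birds, the intercept's
profile interval stays wider than its Wald interval no matter how many
bursts each bird contributes — the between-bird variance is informed
by the number of birds — while contrast intervals converge.

## The synthetic generator

The generator exists so that every stage can be validated against known
truth. `make_landscape()` builds an intertidal elevation ramp (default
-1.8 to +2 m around a 0-2 m tide) with smooth low-frequency relief and
two sinuous channel incisions, then classifies cells: tidal marsh in the
highest band, eelgrass patches preferring the low intertidal, shellfish
in compact patches confined to a narrow band strictly inside the eelgrass
elevation range (so shellfish cells experience a narrower depth
distribution, and few sit high above the waterline), the remainder
unvegetated flats, and a two-cell excluded border. Default class
fractions (41.1 / 35.8 / 2.3 / 20.9%) mirror a temperate estuary with a
small aquaculture footprint. `make_tide()` sums semidiurnal (12.42 h) and
diurnal (25.82 h) constituents, default amplitudes 0.7 and 0.25 m around
a 0.9 m mean.

`simulate_track()` is the discrete-choice inversion of the estimator: at
each 10-min step it draws 100 candidate end points from the current
wetland's kernel and picks one with probability
$\propto \exp(x^\top\beta)$ under the full model. One hundred candidates
(ten times the estimator's available sample) make the discrete choice a
close approximation to the continuous model, so recovery bias from
availability truncation is negligible. Timestamps are confined to
daytime sessions (48 steps from 16:00 UTC, daylight at the reference
longitude year-round) so the daylight filter is exercised but not
destructive; fixes carry ~3 m accuracy and walking speeds.
`simulate_strata()` generates strata directly from the availability
distribution, for estimator validation where a spatial walker's
home-range idiosyncrasies are not the object of study — a single
landscape realisation can starve a walker of encounters with the 2.3%
shellfish class, which is realistic (it is how separation-excluded birds
arise) but makes a poor fixed test condition.

Default generating coefficients encode the qualitative selection
structure the package targets: eelgrass and shellfish attractive,
marsh avoided, a mild concave depth response everywhere, and a strongly
concave shellfish-by-depth² interaction placing peak shellfish
selection near 0.3 m of water with steep decline outside a narrow band.
`simulate_bursts()` emits per-fix tri-axial bursts whose Gaussian noise
scale is calibrated so the expected ODBA equals the wetland's configured
mean (defaults 600 / 750 / 700 / 300 raw units for flats / eelgrass /
shellfish / marsh) plus a per-bird normal offset (SD 80) and burst-level
noise (SD 200, truncated at zero; the truncation bias is ~2% at the
marsh mean and smaller elsewhere).

What the generator does *not* emulate: GPS positional error in the
coordinates themselves (accuracy is metadata only), behavioural states
(roosting vs foraging — the marsh ODBA deficit is generated directly,
not via a state process), prey fields, memory, serial correlation in
selection beyond the movement kernel, and tag failure. Passing recovery
tests therefore demonstrates estimator correctness under the model's own
assumptions, not robustness to their violation in field data.

## Validation problem sizes

The test suite validates parameter recovery end to end with seven birds
of 2,000 steps each on a shared 1.2 × 1.2 km landscape (pooled
inverse-variance estimates within 3 Monte-Carlo SEs of truth), AICc
recovery of the generating model over 20 replicates of 1,000 strata,
Wald-interval coverage for the conditional-logistic core and
likelihood-ratio type-I error for the mixed model over 500 replicates
each, and oracle equivalence of the Newton solver against grid-search
enumeration on 3-stratum toys and against an independent implementation
on larger fixtures. The separation-exclusion behaviour is validated at
2,000 strata per bird, the per-bird data scale the estimator is intended
for; at a few hundred strata the strongly concave shellfish curvature
can legitimately flag quasi-separation in healthy birds.

## Known limitations

- Per-bird models only; between-bird heterogeneity is described, not
  modelled.
- The depth window treats "points" symmetrically for observed and
  available members; if the original filtering intent applied only to
  observed points the stratum counts would differ slightly.
- RSS intervals are Wald; profile intervals for strongly curved
  likelihoods (rare shellfish visits) would be wider.
- GeoTIFF I/O is not provided; grids exchange as ESRI ASCII text.
- The solar-position routine omits atmospheric refraction (~0.1-0.5°
  near the horizon), which shifts the daylight boundary by a couple of
  minutes.
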