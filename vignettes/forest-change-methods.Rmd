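---
title: "Quantifying and attributing change in permanent-plot forest inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and attributing change in permanent-plot forest inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestchange)
```

## The analysis problem

`forestchange` implements a complete analysis chain for repeatedly censused
permanent-plot forest inventories of the kind maintained in Central European
protected mountain landscapes: several thousand 500 m² plots on a systematic
200 × 100 m grid, every stem with diameter at breast height (dbh) of at
least 6 cm recorded, and three censuses spanning roughly three decades
(1984, 1996, 2011 in the default calendar). The chain answers two
questions: *how* is forest structure and composition changing in space and
time (is change accelerating?), and *what drives* the change — legacies of
past stand development, disturbance, climate, or site conditions?

Because inventories of this kind are generally not public, the package
ships a synthetic-landscape generator that produces a full virtual
inventory with *known, recorded* driver effects, so every stage of the
chain can be validated against ground truth.

## Indicators

Nine plot-level indicators are computed from the stem records, each stem
weighted by its expansion factor (stems per hectare it represents; 20 for a
500 m² plot):

* **Structure (4):** basal area (m² ha⁻¹), stand density (n ha⁻¹), density
  of large trees (dbh strictly > 50 cm, n ha⁻¹), and the expansion-weighted
  population standard deviation of dbh (cm).
* **Composition (5):** basal-area shares (%) of conifers and of the
  early-, late-, and rare-seral species classes, and the effective species
  number — the exponential of the Shannon entropy of basal-area
  proportions (the Hill number of order 1).

Two conventions deserve note. The dbh standard deviation uses the
*population* form of the weighted variance: the expansion factors define a
stand-level stem distribution, and the population form is its natural
weighted limit (with equal weights it reduces to the plain population SD).
And the three seral classes need not partition the species list: a species
classed `other` contributes to the conifer share if coniferous but to none
of the seral shares.

## Change, standardization, acceleration

Change is expressed as annualized differences between censuses,
`(value_b − value_a) / (year_b − year_a)`. For mapping, each indicator's
per-plot changes are divided by the maximum *absolute* change observed
across plots, so the largest change has magnitude 1 and signs survive; the
division by a signed maximum would lose the sign structure, which the
hot-spot maps need. Composite change per plot is the mean of the
standardized changes within the structure group and the composition group,
respectively. The group membership (4 structural, 5 compositional) follows
the indicator definitions above.

Acceleration is the landscape mean annual change in the second period
minus that in the first: positive values mean change is speeding up. The
period lengths come from the census calendar (12 and 15 years by default);
per-plot visit dates are not modeled. Change relative to the starting
state divides the period mean change by the landscape mean indicator value
at the first census; it is reported as `NA` when that baseline is zero.

## Spatial patterns

Spatial autocorrelation of standardized change is summarized by a Matheron
empirical semivariogram (15 equal-width lag bins up to one third of the
maximum inter-plot distance) and a weighted-least-squares model fit with
weights `N_j / h_j²` over five families: Spherical, Exponential, Gaussian,
Matérn, and Matérn in Stein's parameterization, the latter two with an
automatic smoothness search over
κ ∈ {0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 1, 1.5, 2, 3, 5, 10}. Several of
these families alias each other exactly (the exponential is the Matérn at
κ = 0.5; Stein's form is a reparameterization of the Matérn on the same κ
grid), so fits whose weighted SSE agree to within a small relative
tolerance are treated as ties and resolved in the family order listed
above. The fitted "effective range" reported by the analysis scripts is
the lag at which the model reaches 95% of its sill — a convention that
must be fixed explicitly because unbounded families never reach the sill.

Interpolation is ordinary kriging at 100 m resolution (cell centres,
extent = plot bounding box padded by one cell): the semivariance system
augmented with the unbiasedness row, solved with one factorization for the
whole grid when all points are used (the default up to 2000 points, which
covers the default scene), or per cell with the nearest neighbors beyond
that. Duplicate plot locations are averaged with a warning; a constant
change field skips kriging and returns the constant surface, since its
semivariogram is degenerate. Pattern similarity between the two periods is
the cell-wise RMSE plus the trend congruence — the percentage of cells
whose interpolated change keeps its sign across periods, with zero
congruent only with zero.

## Driver attribution

Thirty candidate drivers in four categories are assembled per plot and
period: four legacy variables evaluated at the period's *first* census
(development stage, total basal area, stand age as the expansion-weighted
nearest-rank 90th percentile of tree age, and divergence from the
potential natural vegetation), two disturbance variables (management zone,
disturbance occurrence in the period), fifteen climate anomalies (mean
daily temperature, precipitation and radiation for the four meteorological
seasons and the full year, each as the period mean minus the mean over the
full reference span, in daily units), and nine site variables (elevation,
aspect class, roughness, TRI, TPI on the 3 × 3 DEM neighborhood, sand and
clay fractions, soil depth, soil type).

Two of these required an explicit decision where common usage varies:

* **PNV divergence.** The expectation is that the dominant species of the
  potential natural vegetation jointly hold at least 50% of basal area.
  With observed share *s*, divergence is `max(0, (0.5 − s)/0.5) × 100`:
  meeting the expectation gives 0, total absence gives 100. Other
  normalizations are conceivable; this one is bounded, interpretable as
  "percent of the expectation missing", and yields realistic landscape
  means of a few tens of percent.
* **Development stage.** Published stage-classification algorithms are
  decision trees over many stand attributes; the package uses a simplified
  threshold classifier over quadratic mean diameter, stand density and the
  coefficient of variation of dbh that yields the same eight named stages
  (gap/regeneration … decay). It is documented as an approximation and its
  thresholds are exposed (`stage_thresholds()`).

Each of the nine change indicators in each period is regressed on the 30
drivers with gradient-boosted regression trees (squared-error loss,
learning rate 0.01, depth 3, bag fraction 0.5 by default — conventional
BRT practice; all exposed in `brt_config()`). The ensemble size is chosen
by tenfold cross-validation with early stopping. Relative influence is the
per-covariate share of the total squared split improvement; categorical
drivers are one-hot encoded internally and their dummy influences summed
back to the parent before reporting, which keeps importance comparable
across encodings. Backward elimination drops the least influential
covariate, refits with the *same* CV folds (so RMSE differences reflect
covariate sets, not fold noise), and continues to a single covariate; the
candidate with the lowest CV RMSE wins, ties going to the smaller set.
Influences are aggregated across response models weighted by each model's
cross-validated variance explained (negative values clipped to zero;
eliminated covariates contribute zero), renormalized to 100%, and rolled
up by category — overall and separately for structural and compositional
responses. Moran's I with row-standardized 8-nearest-neighbor weights
checks the final-model residuals for spatial autocorrelation against the
null expectation −1/(n−1).

## The synthetic landscape

The generator is a *fixture generator*, not an ecological model: it
reproduces the statistical structure the analysis must detect, not
Alpine forest dynamics. It emulates:

* a 10 m DEM from superposed smooth Gaussian bumps, rescaled exactly to a
  603–2713 m elevation range, with plots placed on the 200 × 100 m grid
  below the 1700 m timberline (150–420 plots depending on the drawn
  terrain; ≈ 300 for the default seed);
* soil fields (sand, clay, depth) as an elevation trend plus Gaussian
  random fields with *recorded* variograms (exact Cholesky simulation on a
  coarse lattice, bilinearly upsampled), a four-class soil-type map, and
  elevation-banded PNV dominants over an eight-species pool with
  early/late/rare seral labels;
* daily climate (temperature, precipitation, radiation) as seasonal
  sinusoids, a −0.0065 °C m⁻¹ lapse, daily noise, and a warming step of
  0.21 °C between the two inter-census periods — the landscape mean of a
  spatially correlated plot-level sensitivity field, with seasonal jitter
  centred so the annual anomaly is the cleanest summary of each plot's
  realized warming;
* annual demography per plot: growth (positive, bounded increments),
  mortality (rising with stand basal area, a one-year pulse on disturbed
  plots), and recruitment at 6–7 cm dbh (Poisson). The recorded truth
  coefficients make warming *amplify* demographic rates
  (`temp_effect`, on the log scale per °C of annual anomaly, also tilting
  recruitment and survival against conifers) and make standing basal area
  *dampen* them (`legacy_damping`), with conifer recruitment increasing
  with elevation. Disturbance covers ~5% of plots per period in random
  rectangular patches.

What it does **not** emulate: seed dispersal, bark-beetle dynamics,
hydrology, realistic age structures, or calibrated demographic rates — no
published rates exist for the emulated inventory, so all constants are
free parameters chosen for plausible desk-scale dynamics and recorded in
`truth.json`. Passing tests therefore demonstrate that the *analysis
chain* recovers imposed effects of realistic shape and magnitude, not that
it would reach identical conclusions on any real inventory.

## Numerical choices and degenerate inputs

* Variogram fits use multiple starts (nugget ∈ {first-bin γ, 0}; range ∈
  {0.1, 0.25, 0.5, 1} × cutoff) of a bounded quasi-Newton optimizer; the
  Matérn uses the Bessel-K form with underflow guards at very small and
  very large scaled lags.
* Kriging with a zero nugget reproduces data values exactly at plot
  locations (checked to 1e−8); weights sum to 1 to 1e−10.
* Empty plots yield all-zero indicators, stage `gap_regeneration`, age 0,
  and PNV divergence 100; an all-zero change field standardizes to zeros
  rather than 0/0.
* Plots exactly at an elevation stratum boundary count as "above"; an
  empty stratum reports `NA` rather than a fabricated difference.
* A constant BRT response returns zero influence with a warning; negative
  cross-validated R² is clipped to zero when used as an aggregation
  weight, and if every model's weight is zero the aggregation falls back
  to an unweighted mean with a warning.
* Boosting uses a fixed RNG seed for fold assignment and bagging, making
  every fit bit-reproducible.

## Problem sizes used by the tests and scripts

The default synthetic scene covers 4 × 2.4 km (≈ 300 plots and ≈ 25,000
tree records for the default seed; the terrain draw moves this between
roughly 150 and 420 plots) — large enough for spatial structure and
tenfold CV, small enough
that the full pipeline runs in minutes on one core. The test suite
validates formulas on closed-form fixtures and brute-force oracles
(100-fold randomized), recovers variogram parameters on noise-free curves
(to 1%) and on simulated Gaussian fields (500 points, to 25%), and runs
the complete end-to-end study on five seeds with a faster boosting
configuration (learning rate 0.1, ≤ 250 trees, early stopping) — the
shrinkage/ensemble-size trade-off leaves CV error nearly unchanged while
keeping the elimination paths affordable. Residual Moran's I is judged by
the median absolute deviation from its null expectation across the 18
final models of a scene: with ~420 plots the per-model sampling SD of I is
≈ 0.02, so individual models fluctuate by several hundredths even for
perfectly unstructured residuals, and the median is the stable summary.

## Known limitations

* The development-stage classifier is a coarse stand-in; stages feed the
  driver models as one categorical covariate, so misclassification
  dilutes but does not bias the legacy signal.
* No edge correction for stems near plot boundaries (none is standard for
  this plot design's data as distributed).
* Kriging is isotropic and unconditional on covariates; no kriging
  variance maps.
* The acceleration statistic is descriptive (means and SDs); no
  significance testing is attached, by design.
* Coordinates are planar metres without CRS handling; geodetic
  reprojection is out of scope.
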