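---
title: "Measuring coastal invasion ranges and competing models of their size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coastal invasion ranges and competing models of their size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastrange)
```

# The measurement model

A coastal benthic invader occupies a quasi one-dimensional habitat: the
shoreline. `coastrange` therefore represents each coastline as a
directed polyline of geographic vertices with a cumulative along-coast
arc length, and a species' distribution on that coast as a set of
positions *s* (km from the first vertex). All geometry is spherical:
great-circle distances use the haversine formula with a fixed Earth
radius of 6371.0 km (`EARTH_RADIUS_KM`), chosen once and documented so
every distance in the package is bit-reproducible. Projection of an
occurrence point onto a coastline interpolates within each polyline
segment by the chord parameter of the corresponding 3-D unit vectors;
placing a point at arc length *s* and projecting it back uses the same
parameterisation, so the two operations are mutually inverse to well
under a metre for vertex spacings of ~1 degree.

Occurrence records are cleaned before measurement. Three rules, each
logged with a reason code: records at exactly (0, 0) are treated as
data-entry artifacts; records farther than a configurable
`offshore_tol_km` (default 100 km, the scale of a one-degree grid
cell) from every coastline are implausible for coastal species —
inland records, misplaced museum specimens; and exact duplicate
coordinates within a species are collapsed. Cleaning never silently
shrinks a dataset: the drop log carries one row per removed record.

Measurement then applies three field rules:

* **Isolated-point floor.** A single isolated occurrence (including a
  locality recorded several times at identical coordinates) scores a
  fixed `isolated_km` = 50 km rather than zero. The floor is the
  method's resolution: no measured range can be smaller.
* **Gap rule.** Neighbouring occurrences more than `gap_km` = 1500 km
  apart do not form a continuous range; the range is split there and
  the pieces tabulated separately. The comparison is strict
  (a gap of exactly 1500 km stays continuous) and — a deliberate
  design decision — is measured *along the coast* (difference of
  *s*), not as a point-to-point chord, because ranges themselves are
  along-coast quantities. Whether the original field protocol used
  along-coast or straight-line neighbour distances is not decidable
  from its description; the along-coast reading is the one consistent
  with measuring ranges along the shoreline, and it is the single
  interpretation applied uniformly to all records, literature-derived
  ones included.
* **Archipelago rule.** Occurrence clusters farther than
  `archipelago_km` = 1000 km from every *continental* coastline have
  no meaningful coastline axis; they are grouped by single-linkage
  agglomeration with a 1000 km linkage radius (reusing the only
  island-scale constant in the rule set) and measured as the
  great-circle distance between the two most separated members — the
  only orientation-free reading of "a straight line through the
  cluster". A singleton cluster scores the 50 km floor.

Per-coast segment lengths and archipelago spans are summed into the
species' total range. A species with no cleaned occurrences yields an
explicit no-range result (`total_km = NA`), never 0 km. Literature
locales reported only as a stretch of coast are discretised into
coordinates every `step_km` = 200 km with the interval end always
included, so the realised span equals the reported extent exactly.

# Climatology covariates

Temperature (°C), salinity (PSU) and current speed (m/s) are stored as
twelve monthly fields on a regular 1° grid with a land mask. A point
samples the cell containing it; a masked cell falls back to the
nearest unmasked cell centre by great-circle distance (ties broken
lexicographically by latitude then longitude) within a 5° search
radius, beyond which the point contributes missing data and is logged.

Seasons are resolved at query time from each point's own hemisphere.
The default convention is three-month blocks anchored at January —
northern winter = Jan–Mar, spring = Apr–Jun (containing the northern
spawning peak that makes spring values mechanistically interesting for
larval transport), summer = Jul–Sep, autumn = Oct–Dec — mirrored by
six months in the south. The December-anchored meteorological
convention is available via `season_months(..., convention = "djf")`.
Because each point uses its own hemisphere's months, a species
straddling the equator mixes the two hemispheres' month blocks; the
grids themselves stay hemisphere-neutral.

Species summaries are computed across occurrence points: mean, sample
standard deviation (n − 1 denominator), minimum and maximum of the
per-point seasonal means, for each variable and season plus the
twelve-month annual aggregate. The annual range reported for
temperature and salinity is the annual maximum statistic minus the
annual minimum statistic — i.e. the spread across the species'
occupied sites of annually averaged conditions. All statistics are
over the same per-point values, so min ≤ mean ≤ max holds exactly.

# The model competition

The estimator of interest is an all-subsets linear-model competition.
`compete_ranges()` takes a formula and data frame, z-scores the
response and every predictor (0/1 dummies included, so coefficients
are standardised betas comparable across variables), and fits OLS by
QR decomposition to all 2^V predictor subsets including the
intercept-only null. Each fit is scored by the small-sample corrected
Akaike criterion with p = k + 2 parameters (intercept, k slopes, error
variance):

$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2p, \qquad
  \mathrm{AICc} = \mathrm{AIC} + \frac{2p(p+1)}{n-p-1}.$$

The Gaussian log-likelihood constant n·ln(2π) + n is omitted; ΔAICc,
Akaike weights and importances are invariant to it (property-tested),
but absolute AICc values are convention-dependent and should only be
compared within one software's output. Weights are
wᵢ = exp(−Δᵢ/2)/Σⱼ exp(−Δⱼ/2). Relative variable importance is the sum
of weights over the models containing a variable among the `top_k` =
40 lowest-AICc fits, with weights renormalised within that subset;
AICc ties at the boundary widen the subset rather than arbitrarily
truncating it. Renormalising over the reported subset (rather than all
2^V models) is one of two defensible conventions; both are
implemented (`weight_mode`), subset renormalisation is the default,
and the choice does not affect model ranks or ΔAICc.

Candidate covariates that are near-duplicates (seasonal variants of
the same field) are pruned before the competition:
`correlation_prune()` clusters variables by connected components of
the |r| > 0.9 graph and keeps one representative per cluster — a
forced variable if present (the spring values of current speed and
temperature are forced by default in the pipeline's configuration,
since spring is the larval-transport window), otherwise the member
most correlated (among |r| > 0.7 partners) with the rest of its
cluster. Constant columns have undefined correlations and are excluded
with a warning.

Coefficient significance flags use two-sided t tests at α = 0.05.
Residual skewness and excess kurtosis of the best model are reported
as diagnostics; no automatic transformation is applied. Missing
predictors are handled by complete-case analysis with a logged drop
count — the upstream data strategy is to drop sparse covariates, not
impute them.

# The synthetic world

The generator exists so that every stage — cleaning, projection,
segmentation, extraction, competition — can be exercised end-to-end
with known ground truth. Its defaults are the study conditions the
package targets: 138 species; first-record years between 1850 and
2012 drawn from a two-piece uniform (half below, half above the
median), which pins the population median year at exactly 1954;
analysis year 2012; true ranges from

range = 37.8 km/yr × (years since first record) + 138 km + noise,

clamped to the 50 km measurement floor and the available coastline;
noise calibrated so the *population* R² of the time-only regression is
0.20 (`noise_sd_for_r2()`: σ² = slope²·Var(t)·(1 − R²)/R²).

**The noise family is the one genuinely open design choice.** With the
intercept (138 km) sitting only 88 km above the 50 km floor and the
calibrated noise SD in the thousands of km, additive Gaussian noise
would put a large share of young species below the floor; clamping
them up censors the left tail and attenuates the recovered slope by
~20% — the generator would contradict its own generative model.
Real range-size data are strongly right-skewed and floor-bounded, so
the generator instead uses *multiplicative* unit-mean gamma noise:
range = μ(t)·G with E[G] = 1 and Var chosen so the implied additive
noise variance σ² = cv²·E[μ²] matches the calibration. This keeps the
conditional mean exactly on the generative line (OLS slope and
intercept recover without bias), makes the floor clamp bind rarely
(young species only, a sub-km slope effect), and produces the
right-skewed range distributions — medians near 1000 km, maxima in
the tens of thousands — that the measured system exhibits. The cost
is mild heteroskedasticity, which inflates the mean *empirical* R² at
n = 138 slightly above the population target (≈ 0.21 vs 0.20).

Trait effects default to small standardised betas (habitat −0.19,
body size +0.15, ambient salinity −0.20) applied to z-scored
predictors and scaled by the implied response SD, so synthetic
competitions qualitatively reproduce a time-dominated importance
ordering; `trait_effects = NULL` gives the pure time-only world used
for parameter recovery. Occurrences are laid along a
generated meandering coastline (length within 0.1% of the request;
vertex spacing ~0.7°, with ~1° connector vertices at the turns so
chord interpolation loses no length) at 100 km spacing with endpoints
always included, which makes measured range equal true range exactly
when gaps stay below 1500 km — the round-trip identity the tests
assert to 0.01 km. Optional off-coast jitter (below the cleaning
tolerance) and split-coast placement exercise the messier paths.

## What passing tests do and do not show

The generator emulates the *geometry and error structure* of the
analysis: floor-censored skewed ranges, coastline-attached occurrence
records, hemisphere-phased seasonal fields, land masking. It does not
emulate record-density biases of public occurrence archives,
taxonomic error, or lags between arrival and first report — a
reported-range world, not a true-range world. Parameter recovery on
synthetic data therefore validates the estimator and the measurement
algebra, not the epidemiology of reporting.

One pipeline behaviour deserves emphasis: covariates that are
*spreads* of environmental fields across a species' occurrences
(e.g. the annual SD of temperature across sites) are mechanically
increasing in range extent whenever the field has a spatial gradient.
In a synthetic world with a clean latitudinal temperature gradient
this reverse causation is strong enough that `temperature_annual_sd`
can outrank the true generative driver in the full-pipeline
competition. This is a property of the measured system (real analyses
share it in attenuated form), not of the estimator; the tests
therefore check importance recovery on responses simulated from the
design matrix, where "only time active" is actually true, and check
the full pipeline for structural invariants (model counts, weight
normalisation, ΔAICc of the best model).

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty position vectors give
empty segment tables; species with zero cleaned points give no-range
results; fully masked grids, inverted locale intervals, rank-deficient
designs and insufficient sample for the AICc correction all raise
named errors. The all-subsets guard refuses more than 20 predictors
(2^20 fits) unless overridden.

The shipped tests and the acceptance script use the sizes the package
treats as its reference conditions: 1000 random position vectors
against a brute-force segmentation oracle; worlds of 25–50 species for
round-trip identities; 200 replicates of 138 species for slope and R²
recovery (mean slope within two Monte-Carlo standard errors of 37.8;
mean R² within 0.03 of 0.20); and the full 2048-model competition at
n = 138. A complete run of suite plus acceptance script takes on the
order of ten minutes on one CPU.

# Limitations

* Shorelines are user-supplied polylines; the package does no
  shoreline simplification or generalisation, and range values depend
  on the resolution of the supplied coastline as they do for any
  along-coast method.
* Gridded inputs are read from dense CSV (lat, lon, month, value);
  NetCDF sources should be exported to that layout first.
* The competition is plain OLS: no mixed models, no spatial
  autocorrelation corrections, no multiple-testing machinery beyond
  per-coefficient flags.
* Tree-based robustness checks (random forests, boosted trees) are
  intentionally out of scope; they are third-party algorithms best run
  from their own packages on the exported analysis table.
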