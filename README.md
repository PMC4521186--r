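# coastrange

Marine invertebrates introduced outside their native range spread along
coastlines, and how far they have spread is among the most consequential
and most measurable quantities in invasion ecology. `coastrange`
implements, as a tested and reusable pipeline, the analysis linking the
**non-native coastal range size** of benthic marine invertebrates to
**time since first global introduction**, species traits, and the
climatology of the recipient environment. It is aimed at spatial
ecologists and invasion biologists who want the range-quantification
rules, the covariate extraction, and the information-theoretic model
competition as programmable building blocks instead of manual GIS work.

The package has four parts:

1. **Along-coast range quantification.** Coastlines are ordered
   geographic polylines carrying a cumulative arc length, so a position
   on a coast is a single number *s* (km). Occurrence coordinates are
   cleaned (records at (0, 0), inland/implausible records, duplicates),
   projected onto their nearest coastline, and converted into disjoint
   range segments under three field rules: a single isolated occurrence
   scores a fixed 50 km; neighbouring occurrences more than 1500 km
   apart along the coast split the range; occurrence clusters more than
   1000 km from every continental coastline are treated as oceanic
   archipelagos and measured as the straight-line span through the
   cluster. Per-coast segment lengths are summed into the species'
   total range (km). Literature locales ("coast of X") can be
   discretised into coordinates every 200 km.
2. **Climatology covariates.** Temperature, salinity and current speed
   are sampled at occurrence points from 1° monthly grids (nearest
   unmasked cell; seasons resolved per point's hemisphere), and
   summarised per species as seasonal/annual mean, SD, min, max, plus
   annual ranges.
3. **Model competition.** The central estimator, `compete_ranges()`,
   z-scores the response and predictors, fits ordinary least squares to
   every subset of the candidate predictors (2^V models including the
   intercept-only null), ranks them by the small-sample corrected
   Akaike criterion

   AICc = n·ln(RSS/n) + 2p + 2p(p+1)/(n−p−1),  p = k + 2,

   converts criterion differences Δᵢ to Akaike weights
   wᵢ = exp(−Δᵢ/2)/Σⱼ exp(−Δⱼ/2), and scores each variable's relative
   variable importance (RVI) as the sum of weights over the 40
   best models containing it. Correlated candidate covariates can be
   pruned beforehand (`correlation_prune()`, clusters at |r| > 0.9,
   one representative chosen among |r| > 0.7 partners).
4. **A synthetic world.** `simulate_world()` generates coastlines,
   climatologies, species (traits, first-record years with median 1954)
   and occurrence points whose true ranges follow a stated linear model
   in time since introduction — so the whole pipeline is testable
   end-to-end with known ground truth, and parameter recovery can be
   checked.

## Worked example

Simulate a 138-species world from the time-only generative model
(slope 37.8 km/year, intercept 138 km, noise calibrated to a population
R² of 0.20), measure every species' range through the full
cleaning/projection/segmentation path, and fit the time-only
regression:

```r
library(coastrange)

cfg <- world_config(seed = 11, n_species = 138, trait_effects = NULL)
w   <- simulate_world(cfg)
m   <- measure_ranges(w$occurrences, w$coastlines)

summary(m$totals$total_km)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    50.0   435.3  1239.5  3016.1  4026.2 26644.1

d <- merge(m$totals, w$species, by = "species_id")
f <- lm(total_km ~ time_since_introduction, d)
coef(f)
#>             (Intercept) time_since_introduction
#>               353.42539                40.73285
summary(f)$r.squared
#> [1] 0.1922618
```

Measured ranges span the 50 km floor to ~27,000 km, strongly
right-skewed, and the recovered slope (40.7 km/year here; 37.8 on
average across replicates) says a typical invader's measured coastal
range grows by roughly 400 km per decade of residence. A single
replicate's R² scatters around the calibrated 0.20.

The full competition over the eleven standard predictors runs as:

```r
res <- run_pipeline(world_config(seed = 11), out_dir = "run1")
print(res$competition)   # 2048 ranked models, standardised betas, RVI
summary(res$competition) # best models per size, null model, importances
```

`run_pipeline()` writes every intermediate table (range segments and
totals, drop log, environmental summaries, analysis table, ranked model
table, waterfall latitudinal bands) plus the resolved configuration
next to its outputs. Note one instructive behaviour of the full
pipeline: the across-occurrence SD of a latitude-graded field (e.g.
`temperature_annual_sd`) is mechanically coupled to range extent
itself, so it competes with — and can outrank — the true generative
driver; see the methods vignette for why this reverse causation arises
and how the package's tests separate it from estimator behaviour.

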