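test_that("generated coastlines hit the requested length and are reproducible", {
  set.seed(71)
  cl <- make_coastline(10000)
  expect_equal(cl$length_km, 10000, tolerance = 1e-3)
  set.seed(71)
  cl2 <- make_coastline(10000)
  expect_identical(cl$lat, cl2$lat)
  expect_identical(cl$lon, cl2$lon)
  expect_error(make_coastline(-5), "degenerate")
})

test_that("island clusters sit beyond the archipelago distance from the coast", {
  set.seed(72)
  cl <- make_coastline(8000)
  isl <- make_island_points(cl, offset_km = 1200, n = 4)
  d <- coast_project(cl, isl$lat, isl$lon)$offshore_km
  expect_true(all(d > 1000))
})

test_that("synthetic climatologies impose gradient, phase and resolution", {
  set.seed(73)
  cl <- make_coastline(30000)
  g <- make_climatology(cl)
  tg <- g$temperature
  expect_equal(diff(tg$lat), rep(1, length(tg$lat) - 1))
  eq <- which.min(abs(tg$lat - 0.5))
  hi <- which.min(abs(tg$lat - 60.5))
  lo <- which.min(abs(tg$lat + 60.5))
  open <- which(!tg$mask[eq, ])[1]
  # equator warmer than 60 degrees in the same season
  expect_gt(tg$values[eq, open, 7], tg$values[hi, open, 7])
  # northern cells peak in NH summer, southern cells in SH summer
  expect_gt(mean(tg$values[hi, open, 7:9]), mean(tg$values[hi, open, 1:3]))
  expect_lt(mean(tg$values[lo, open, 7:9]), mean(tg$values[lo, open, 1:3]))
  # a land band is masked
  expect_true(any(tg$mask))
  expect_gte(min(g$current_speed$values, na.rm = TRUE), 0.01)
})

test_that("noise calibration follows the closed form and achieves the target R-squared", {
  expect_equal(noise_sd_for_r2(2, 9, 0.5), sqrt(4 * 9), tolerance = 1e-12)
  expect_equal(noise_sd_for_r2(2, 9, 0.999), sqrt(4 * 9 * 0.001 / 0.999),
               tolerance = 1e-12)
  expect_error(noise_sd_for_r2(2, 9, 1.2), "target_r2")
  set.seed(74)
  n <- 10000
  x <- runif(n, 0, 160)
  sig <- noise_sd_for_r2(37.8, var(x), 0.2)
  y <- 37.8 * x + rnorm(n, 0, sig)
  expect_equal(summary(lm(y ~ x))$r.squared, 0.2, tolerance = 0.02)
})

test_that("simulated species honour the configured sizes, median year and floor", {
  cfg <- world_config(seed = 75)
  set.seed(cfg$seed)
  sp <- simulate_species(cfg)
  expect_equal(nrow(sp), 138)
  expect_lte(abs(median(sp$year) - 1954), 5)
  expect_true(all(sp$true_range_km >= 50))
  expect_true(all(sp$true_range_km <= cfg$coast_length_km))
  expect_true(all(sp$year >= 1850 & sp$year <= 2012))
  expect_setequal(unique(sp$habitat), c("epifaunal", "infaunal"))
  tr <- attr(sp, "truth")
  expect_equal(tr$slope, 37.8)
  # configuration validation
  expect_error(world_config(target_r2 = 1.2), "target_r2")
  expect_error(world_config(median_year = 1800), "median_year")
  expect_error(world_config(target_r2 = 0.5, noise_sd = 10), "not both")
})

test_that("identical configurations reproduce identical worlds", {
  cfg <- world_config(seed = 76, n_species = 12)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$species, w2$species)
  expect_identical(w1$occurrences, w2$occurrences)
  expect_identical(w1$coastlines[[1]]$lon, w2$coastlines[[1]]$lon)
  expect_identical(w1$grids$temperature$values,
                   w2$grids$temperature$values)
})

test_that("placed occurrences span exactly the true range through the measurement rules", {
  cfg <- world_config(seed = 77, n_species = 25, trait_effects = NULL)
  w <- simulate_world(cfg)
  m <- measure_ranges(w$occurrences, w$coastlines)
  d <- merge(m$totals, w$species[c("species_id", "true_range_km")],
             by = "species_id")
  expect_equal(d$total_km, d$true_range_km, tolerance = 1e-5)
  # single-point species measure the floor exactly
  small <- d$true_range_km <= 50
  if (any(small)) expect_true(all(d$total_km[small] == 50))
})

test_that("a split-coast species' sub-ranges add to its true range", {
  set.seed(78)
  c1 <- make_coastline(12000, id = "c1")
  set.seed(79)
  c2 <- make_coastline(12000, id = "c2", lon_start = 120)
  cfg <- world_config(seed = 80, n_species = 10, split_prob = 1,
                      coast_length_km = 12000, trait_effects = NULL)
  sp <- local({set.seed(cfg$seed); simulate_species(cfg)})
  set.seed(cfg$seed + 1)
  occ <- place_occurrences(sp, list(c1, c2), cfg)
  m <- measure_ranges(occ, list(c1, c2))
  d <- merge(m$totals, sp[c("species_id", "true_range_km")],
             by = "species_id")
  expect_equal(d$total_km, d$true_range_km, tolerance = 1e-5)
  split_sp <- d$species_id[d$true_range_km > 2 * cfg$isolated_km]
  if (length(split_sp)) {
    seg <- m$segments[m$segments$species_id == split_sp[1], ]
    expect_setequal(unique(seg$coastline_id), c("c1", "c2"))
  }
})

test_that("written worlds round-trip through the package readers", {
  cfg <- world_config(seed = 81, n_species = 6)
  w <- simulate_world(cfg)
  td <- file.path(tempdir(), "worldout")
  paths <- write_world(w, td)
  occ <- read_occurrences(paths$occurrences)
  expect_equal(nrow(occ), nrow(w$occurrences))
  cls <- read_coastlines_geojson(paths$coastlines)
  expect_equal(cls[[1]]$length_km, w$coastlines[[1]]$length_km,
               tolerance = 1e-6)
  g <- read_climatology_csv(paths$clim_temperature, "temperature")
  expect_equal(g$values, w$grids$temperature$values)
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$slope, 37.8)
})
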