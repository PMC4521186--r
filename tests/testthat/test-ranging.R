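test_that("segmenting applies the isolated-point and gap rules", {
  one <- segment_coast_positions(100)
  expect_equal(one$length_km, 50)
  expect_true(one$is_isolated)

  two <- segment_coast_positions(c(100, 300))
  expect_equal(nrow(two), 1)
  expect_equal(two$length_km, 200)

  split <- segment_coast_positions(c(100, 1700))   # gap 1600 > 1500
  expect_equal(nrow(split), 2)
  expect_equal(sum(split$length_km), 100)

  mix <- segment_coast_positions(c(0, 700, 1400, 3200))
  expect_equal(mix$length_km, c(1400, 50))
  expect_equal(mix$n_points, c(3L, 1L))

  # split is strict: a gap of exactly 1500 km stays continuous
  expect_equal(nrow(segment_coast_positions(c(0, 1500))), 1)
  expect_equal(nrow(segment_coast_positions(c(0, 1500.001))), 2)

  expect_equal(nrow(segment_coast_positions(numeric(0))), 0)
})

test_that("segmenting matches the brute-force grouping oracle on random position vectors", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    s <- runif(n, 0, 12000)
    seg <- segment_coast_positions(s)
    expect_identical(sum(seg$length_km), oracle_segment_total(s))
    # segments are disjoint and in order
    if (nrow(seg) > 1) {
      expect_true(all(diff(seg$s_start) > 0))
      expect_true(all(seg$s_start[-1] - seg$s_end[-nrow(seg)] > 1500))
    }
  }
})

test_that("archipelago spans are the maximum pairwise great-circle distance", {
  expect_equal(archipelago_range(10, 100), 50)
  d2 <- great_circle_km(0, 0, 0, 3)
  expect_equal(archipelago_range(c(0, 0), c(0, 3)), d2)
  # near-collinear cluster: span is between the two extremes
  lat <- c(0, 0, 0); lon <- c(0, 1.5, 3.2)
  expect_equal(archipelago_range(lat, lon),
               great_circle_km(0, 0, 0, 3.2))
  expect_error(archipelago_range(numeric(0), numeric(0)), "empty")
})

test_that("total range composes coasts and archipelagos additively", {
  cl <- meridional_coast(40, id = "main")
  # one coastal point plus one distant island point: 50 + 50
  pts <- data.frame(species_id = "s", lat = c(5, 5), lon = c(0.1, 60))
  asg <- assign_points(pts, cl)
  r <- total_range("s", asg)
  expect_equal(r$total_km, 100)
  expect_equal(nrow(r$segments), 2)

  # a single point gives exactly the floor
  r1 <- total_range("s", assign_points(
    data.frame(species_id = "s", lat = 5, lon = 0.05), cl))
  expect_equal(r1$total_km, 50)

  # spans on two coasts add up
  c2 <- coastline(seq(0, 40, 0.5), rep(90, 81), id = "second")
  span1 <- data.frame(species_id = "s", lat = c(1, 2, 3, 4), lon = 0)
  span2 <- data.frame(species_id = "s", lat = c(10, 13), lon = 90)
  asg2 <- assign_points(rbind(span1, span2), list(cl, c2))
  r2 <- total_range("s", asg2)
  per_coast <- tapply(r2$segments$length_km, r2$segments$coastline_id, sum)
  expect_equal(r2$total_km, sum(per_coast))
  expect_equal(unname(per_coast["main"]),
               great_circle_km(1, 0, 4, 0), tolerance = 1e-3)

  # zero cleaned points: an explicit no-range result, not 0 km
  r0 <- total_range("absent", asg)
  expect_true(r0$no_range)
  expect_true(is.na(r0$total_km))
})

test_that("total range is invariant to point order and duplicates and bounded by the span", {
  set.seed(42)
  cl <- meridional_coast(60)
  for (i in 1:20) {
    n <- sample(1:10, 1)
    lat <- round(runif(n, 0, 60), 3)
    pts <- data.frame(species_id = "s", lat = lat, lon = 0)
    asg <- assign_points(pts, cl)
    base <- total_range("s", asg)$total_km
    shuf <- pts[sample(n), , drop = FALSE]
    dup <- rbind(pts, pts[1, ])
    expect_equal(total_range("s", assign_points(shuf, cl))$total_km, base)
    expect_equal(total_range("s", assign_points(dup, cl))$total_km, base)
    span <- diff(range(coast_project(cl, pts$lat, pts$lon)$s))
    expect_gte(base, 50)
    expect_lte(base, span + 50 + 1e-9)
  }
})

test_that("locale discretisation includes endpoints and round-trips through measurement", {
  cl <- meridional_coast(15)
  p <- locale_to_points(cl, 0, 1000, step_km = 200)
  expect_equal(nrow(p), 6)
  expect_equal(p$s, seq(0, 1000, 200))
  expect_equal(unique(p$source), "literature")

  p2 <- locale_to_points(cl, 0, 0)
  expect_equal(nrow(p2), 1)

  p3 <- locale_to_points(cl, 0, 500, step_km = 200)
  expect_equal(p3$s, c(0, 200, 400, 500))
  expect_error(locale_to_points(cl, 10, 5), "inverted")

  # discretise-then-measure returns exactly the locale extent
  for (iv in list(c(0, 1000), c(120, 870), c(300, 1500))) {
    pts <- locale_to_points(cl, iv[1], iv[2], step_km = 200,
                            species_id = "loc")
    asg <- assign_points(pts[c("species_id", "lat", "lon")], cl)
    expect_equal(total_range("loc", asg)$total_km, iv[2] - iv[1],
                 tolerance = 1e-6)
  }
})

test_that("measure_ranges produces per-species totals, logs and exports", {
  cl <- meridional_coast(30, id = "main")
  pts <- rbind(
    data.frame(species_id = "a", lat = c(1, 3), lon = 0, source = "gbif"),
    data.frame(species_id = "b", lat = 10, lon = 0.1, source = "gbif"),
    data.frame(species_id = "b", lat = 0, lon = 0, source = "gbif"))
  m <- measure_ranges(pts, cl)
  expect_equal(m$totals$species_id, c("a", "b"))
  expect_equal(m$totals$total_km[2], 50)        # b keeps one valid point
  expect_equal(m$drops$reason, "zero-zero")
  td <- tempfile(); dir.create(td)
  write_ranges_csv(m, file.path(td, "seg.csv"), file.path(td, "tot.csv"))
  expect_true(file.exists(file.path(td, "tot.csv")))
  back <- read.csv(file.path(td, "tot.csv"))
  expect_equal(back$total_km, m$totals$total_km)
})
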