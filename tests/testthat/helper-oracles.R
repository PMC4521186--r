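# fixtures and independent brute-force oracles used across test files

# simple meridional coastline: lon = 0, lat from 0 to `lat_top`, vertex
# every `step_deg` degrees
meridional_coast <- function(lat_top = 10, step_deg = 0.5, ...) {
  lats <- seq(0, lat_top, by = step_deg)
  coastline(lats, rep(0, length(lats)), ...)
}

# nearest point on a polyline by dense sampling of the interpolated path
oracle_project <- function(coast, lat, lon, ds = 0.2) {
  ss <- seq(0, coast$length_km, by = ds)
  dense <- coast_point_at(coast, ss)
  vapply(seq_along(lat), function(i) {
    dd <- great_circle_km(lat[i], lon[i], dense[, 1], dense[, 2])
    k <- which.min(dd)
    c(s = ss[k], d = dd[k])
  }, c(s = 0, d = 0))
}

# brute-force grouping: walk sorted positions, cut at gaps > gap_km,
# score each group independently
oracle_segment_total <- function(s, gap_km = 1500, isolated_km = 50) {
  if (!length(s)) return(0)
  s <- sort(s)
  total <- 0
  start <- 1
  for (i in seq_along(s)) {
    if (i == length(s) || s[i + 1] - s[i] > gap_km) {
      total <- total + if (i == start) isolated_km else s[i] - s[start]
      start <- i + 1
    }
  }
  total
}

# connected components of the "within linkage_km" graph by repeated
# label propagation (independent of hclust)
oracle_components <- function(dmat, linkage_km) {
  n <- nrow(dmat)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (dmat[i, j] <= linkage_km && lab[j] > lab[i]) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# normal-equations least squares: (X'X)^{-1} X'y
oracle_ols <- function(y, X) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# exhaustive nearest-unmasked-cell search on a climatology grid
oracle_nearest_cell <- function(grid, lat, lon) {
  best <- NULL; bestd <- Inf
  for (i in seq_along(grid$lat)) for (j in seq_along(grid$lon)) {
    if (grid$mask[i, j]) next
    d <- great_circle_km(lat, lon, grid$lat[i], grid$lon[j])
    if (d < bestd - 1e-9 ||
        (abs(d - bestd) <= 1e-9 &&
         (grid$lat[i] < grid$lat[best[1]] ||
          (grid$lat[i] == grid$lat[best[1]] &&
           grid$lon[j] < grid$lon[best[2]])))) {
      bestd <- d; best <- c(i, j)
    }
  }
  list(idx = best, d = bestd)
}

# small all-ocean constant-free grid: value = base + lat_coef*lat +
# month_coef*month, optionally masked cells
toy_grid <- function(variable = "temperature", lats = seq(-4.5, 4.5, 1),
                     lons = seq(0.5, 9.5, 1), base = 10, lat_coef = 0,
                     month_coef = 0, mask_cells = NULL) {
  arr <- array(NA_real_, c(length(lats), length(lons), 12))
  for (m in 1:12)
    arr[, , m] <- outer(base + lat_coef * lats, rep(1, length(lons))) +
      month_coef * m
  if (!is.null(mask_cells))
    for (k in seq_len(nrow(mask_cells)))
      arr[mask_cells[k, 1], mask_cells[k, 2], ] <- NA
  climatology(variable, lats, lons, arr)
}
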